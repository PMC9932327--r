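# Trace-based STDP/LTD at the parallel-fiber inputs. Presynaptic traces x_j
# (one per stimulated compartment) mark recent pulses; a postsynaptic trace
# y marks the climbing-fiber (CF) instruction signal. Weight rule per
# plasticity tick:
#   dw_j = -A1 * y * S_j + A2 * x_j * S + A3,   clamped to [w_min, w_max]
# with the study's constants A1 = 0.9, A2 = 0 (LTD only), A3 = 0.001 (slow
# AMPA-receptor reinsertion). Updates run on a dedicated tick (default 1 ms)
# decoupled from the solver step, so A3's cumulative effect is
# dt-independent. Weight dynamics depend only on event times, never on
# voltage, so the rule is deterministic given the protocol.

#' Plasticity rule constants
#'
#' @param tau_pre presynaptic trace time constant, ms.
#' @param tau_post CF trace time constant, ms.
#' @param a1 LTD amplitude (pairing of CF trace with a pulse).
#' @param a2 LTP amplitude (0 in the LTD-only setting).
#' @param a3 constant drift per plasticity tick (receptor reinsertion).
#' @param w_min,w_max weight clamp bounds, nA.
#' @param tick weight-update clock, ms.
#' @return List of class `plasticity_params`.
#' @export
plasticity_params <- function(tau_pre = 100, tau_post = 100,
                              a1 = 0.9, a2 = 0, a3 = 0.001,
                              w_min = 0, w_max = 12.87, tick = 1) {
  stopifnot(tau_pre > 0, tau_post > 0, tick > 0, w_min <= w_max)
  structure(list(tau_pre = tau_pre, tau_post = tau_post, a1 = a1, a2 = a2,
                 a3 = a3, w_min = w_min, w_max = w_max, tick = tick),
            class = "plasticity_params")
}

#' Advance an eligibility trace one step
#'
#' `x' = exp(-dt/tau) * x + S`.
#'
#' @param x current trace value(s), dimensionless, >= 0.
#' @param S event indicator(s), 0 or 1.
#' @param dt elapsed time, ms (> 0).
#' @param tau trace time constant, ms.
#' @return Updated trace value(s).
#' @export
update_trace <- function(x, S, dt, tau) {
  stopifnot(dt > 0, tau > 0)
  exp(-dt / tau) * x + S
}

#' Trace state for a stimulated path
#'
#' @param path compartment ids carrying plastic weights.
#' @param w initial weights, nA (scalar or per-compartment).
#' @return List of class `trace_state` with presynaptic traces `x` (named by
#'   compartment), CF trace `y`, and weights `w`.
#' @export
trace_state <- function(path, w) {
  ids <- as.character(path)
  w <- if (length(w) == 1) setNames(rep(w, length(ids)), ids) else {
    stopifnot(length(w) == length(ids)); setNames(as.numeric(w), ids)
  }
  structure(list(x = setNames(rep(0, length(ids)), ids), y = 0, w = w),
            class = "trace_state")
}

#' Apply one plasticity tick to the weights
#'
#' `w_j <- clamp(w_j - a1 * y * S_j + a2 * x_j * S + a3, w_min, w_max)`.
#' Weights pushed negative clamp to `w_min`; weights above `w_max` fix there.
#'
#' @param ts a [trace_state()] whose traces are current as of this tick.
#' @param S_j per-compartment pulse indicators (0/1), in `ts$x` order.
#' @param S CF indicator (0/1).
#' @param p a [plasticity_params()].
#' @return Updated `trace_state`.
#' @export
weight_update <- function(ts, S_j, S, p) {
  stopifnot(inherits(ts, "trace_state"), length(S_j) == length(ts$w))
  dw <- -p$a1 * ts$y * S_j + p$a2 * ts$x * S + p$a3
  ts$w <- pmin(pmax(ts$w + dw, p$w_min), p$w_max)
  ts
}

#' Learning protocol: pulse sequence paired with a delayed CF event
#'
#' @param sequence a [pulse_train()]; its (possibly per-compartment) weights
#'   are the initial plastic weights.
#' @param cf_delay CF delay after the end of stimulation, ms.
#' @param trial_duration total trial length, ms.
#' @param presentations sequence repetitions within the trial, evenly spaced
#'   (1 reproduces the single-pairing protocol; with CF strictly after all
#'   pulses the LTD term is then inert and only the A3 drift acts — use >= 2
#'   for the CF trace of one presentation to overlap the next).
#' @param learning_enabled logical; when `FALSE` the weights are untouched.
#' @return List of class `learning_protocol`.
#' @export
learning_protocol <- function(sequence, cf_delay = 2, trial_duration = 5000,
                              presentations = 1, learning_enabled = TRUE) {
  stopifnot(inherits(sequence, "pulse_train"), cf_delay >= 0, presentations >= 1)
  seq_span <- sequence$duration_physical + cf_delay
  slot <- trial_duration / presentations
  if (sequence$onset + seq_span > slot) {
    stop("learning_protocol: CF time ", sequence$onset + seq_span,
         " ms exceeds the per-presentation window of ", slot, " ms")
  }
  structure(list(sequence = sequence, cf_delay = cf_delay,
                 trial_duration = trial_duration,
                 presentations = presentations,
                 learning_enabled = isTRUE(learning_enabled)),
            class = "learning_protocol")
}

# event times for one trial: per-compartment pulse onsets and CF times
.learning_events <- function(lp) {
  s <- lp$sequence
  slot <- lp$trial_duration / lp$presentations
  sched1 <- schedule(s)
  pulses <- do.call(rbind, lapply(seq_len(lp$presentations) - 1L, function(k) {
    d <- sched1
    d$t_ms <- d$t_ms + k * slot
    d
  }))
  cf_times <- (seq_len(lp$presentations) - 1L) * slot + s$onset +
    s$duration_physical + lp$cf_delay
  list(pulses = pulses, cf_times = cf_times)
}

#' Run a learning trial and return the updated weights
#'
#' Advances the presynaptic and CF traces on the plasticity tick grid over
#' the whole trial, applying the weight rule at every tick while learning is
#' enabled. Pulse events land on the tick containing their onset; the CF
#' event on the tick containing the CF time. Later pulses of the trial use
#' the weights current at their onset. Optionally also integrates the
#' membrane model under the same (weight-trajectory-correct) stimulus.
#'
#' @param lp a [learning_protocol()].
#' @param p a [plasticity_params()].
#' @param m,cs,cfg morphology, channel set and solver config; only needed
#'   when `run_solver = TRUE`.
#' @param run_solver logical; when `TRUE`, also returns the somatic trace of
#'   the trial.
#' @return List with `w` (final weights, named by compartment), `w0`
#'   (initial), `log` (data.frame: tick times, y trace, mean weight), and
#'   `trace` (a `recorded_trace`, or `NULL`).
#' @export
learning_trial <- function(lp, p = plasticity_params(), m = NULL, cs = NULL,
                           cfg = solver_config(), run_solver = FALSE) {
  stopifnot(inherits(lp, "learning_protocol"), inherits(p, "plasticity_params"))
  s <- lp$sequence
  ts <- trace_state(s$path, s$weight)
  ev <- .learning_events(lp)
  n_ticks <- ceiling(lp$trial_duration / p$tick)
  pulse_tick <- floor(ev$pulses$t_ms / p$tick) + 1L
  cf_tick <- floor(ev$cf_times / p$tick) + 1L
  ids <- as.character(s$path)
  w_at_pulse <- numeric(nrow(ev$pulses))     # weight in force at each pulse
  log_t <- numeric(n_ticks); log_y <- numeric(n_ticks); log_wmean <- numeric(n_ticks)

  for (k in seq_len(n_ticks)) {
    S_j <- setNames(numeric(length(ids)), ids)
    hit <- which(pulse_tick == k)
    if (length(hit) > 0) {
      S_j[as.character(ev$pulses$compartment[hit])] <- 1
      w_at_pulse[hit] <- ts$w[as.character(ev$pulses$compartment[hit])]
    }
    S <- as.numeric(any(cf_tick == k))
    ts$x <- update_trace(ts$x, S_j, p$tick, p$tau_pre)
    ts$y <- update_trace(ts$y, S, p$tick, p$tau_post)
    if (lp$learning_enabled) ts <- weight_update(ts, S_j, S, p)
    log_t[k] <- k * p$tick; log_y[k] <- ts$y; log_wmean[k] <- mean(ts$w)
  }

  trace <- NULL
  if (run_solver) {
    if (is.null(m) || is.null(cs)) stop("learning_trial: run_solver needs m and cs")
    proto <- ev$pulses
    proto$w_nA <- w_at_pulse
    attr(proto, "pulse_width") <- s$pulse_width
    attr(proto, "mode") <- s$mode
    attr(proto, "tau_i") <- s$tau_i
    trace <- run(m, cs, proto, cfg, t_stop = lp$trial_duration)
  }
  list(w = ts$w, w0 = trace_state(s$path, s$weight)$w,
       log = data.frame(t_ms = log_t, y = log_y, w_mean = log_wmean),
       trace = trace)
}

#' Search for sequences whose preferred direction reverses with learning
#'
#' For every triplet of `before` that evoked a response in at least one
#' direction: run a learning trial on the responsive direction's sequence
#' (IN if both responded), then re-evaluate both directions with learning
#' off using the learned per-compartment weights, and compare classes.
#'
#' @param m a `pc_morphology`.
#' @param cs a `channel_set`.
#' @param pairs sequence pairs from [grid_sequences()].
#' @param before sweep result for `pairs` (see [run_sweep()]), learning off.
#' @param p a [plasticity_params()].
#' @param cf_delay,trial_duration,presentations learning-protocol settings,
#'   applied to every responsive sequence.
#' @param cfg a [solver_config()].
#' @param det a [spike_detector_config()].
#' @param init optional settled `sim_state` reused across evaluations.
#' @return List with `table` (data.frame: n_pulses, interval, weight,
#'   class_before, class_after) and `flipped` (rows whose exclusive
#'   direction reversed: IN_ONLY -> OUT_ONLY or OUT_ONLY -> IN_ONLY).
#' @export
reversal_search <- function(m, cs, pairs, before, p = plasticity_params(),
                            cf_delay = 2, trial_duration = 5000,
                            presentations = 1,
                            cfg = solver_config(), det = spike_detector_config(),
                            init = NULL) {
  stopifnot(nrow(before) == length(pairs))
  if (is.null(init)) init <- init_state(m, cs, cfg)
  rows <- list()
  for (i in seq_len(nrow(before))) {
    b <- before[i, ]
    if (!(b$spiked_in || b$spiked_out)) next
    pair <- pairs[[i]]
    learn_seq <- if (b$spiked_in) pair$in_train else pair$out_train
    lp <- learning_protocol(learn_seq, cf_delay = cf_delay,
                            trial_duration = trial_duration,
                            presentations = presentations)
    learned <- learning_trial(lp, p)
    in2 <- pair$in_train; in2$weight <- learned$w
    out2 <- pair$out_train; out2$weight <- learned$w
    res_in <- .spiked(m, cs, in2, cfg, det, init)
    res_out <- .spiked(m, cs, out2, cfg, det, init)
    rows[[length(rows) + 1L]] <- data.frame(
      n_pulses = b$n_pulses, interval_ms = b$interval_ms, weight_nA = b$weight_nA,
      class_before = b$class, class_after = classify(res_in, res_out))
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(n_pulses = integer(0), interval_ms = numeric(0),
               weight_nA = numeric(0), class_before = character(0),
               class_after = character(0))
  flips <- tab[(tab$class_before == "IN_ONLY" & tab$class_after == "OUT_ONLY") |
               (tab$class_before == "OUT_ONLY" & tab$class_after == "IN_ONLY"), ,
               drop = FALSE]
  list(table = tab, flipped = flips)
}

# run one pulse train and report whether the soma spiked in the response
# window [first onset, last offset + grace]
.spiked <- function(m, cs, train, cfg, det, init) {
  sched <- schedule(train)
  t_last <- max(sched$t_ms) + train$pulse_width
  tr <- run(m, cs, sched, cfg, t_stop = t_last + det$grace, init = init)
  sp <- detect_spikes(tr, det)
  any(sp >= min(sched$t_ms) & sp <= t_last + det$grace)
}
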