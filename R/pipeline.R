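# Experiment runners: the discrimination sweep, the calcium-channel
# time-constant scan, and the learning/reversal experiment. Each runner is
# deterministic for a fixed configuration; outputs are CSV row tables plus a
# JSON summary embedding a configuration hash and the package version.

# Polynomial rolling hash over the JSON serialization: a stable content
# hash without extra dependencies (not cryptographic; used only to tie
# outputs to configs). Arithmetic stays below 2^53 so doubles are exact.
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.pkg_version <- function() as.character(utils::packageVersion("pcseq"))

#' Run a discrimination sweep over a parameter grid
#'
#' For every (n_pulses, interval, weight) triplet of the grid, simulates the
#' IN and OUT presentation on the same compartments, detects somatic spikes
#' in the response window, and classifies the pair. The settled initial
#' state is computed once and reused, so rows are independent and the result
#' is deterministic in grid order.
#'
#' @param m a `pc_morphology`.
#' @param cs a `channel_set`.
#' @param grid a [sweep_grid()].
#' @param cfg a [solver_config()].
#' @param det a [spike_detector_config()].
#' @param mode,tau_i pulse shape (see [pulse_train()]).
#' @param max_cells optional truncation: evaluate only the first `max_cells`
#'   triplets (desk-scale runs).
#' @param outdir optional output directory; writes `sweep.csv` and
#'   `sweep_summary.json`.
#' @param init optional pre-settled `sim_state`.
#' @return data.frame with one row per evaluated triplet: `n_pulses`,
#'   `interval_ms`, `weight_nA`, `spiked_in`, `spiked_out`, `class`;
#'   attributes `ctype` (of the start compartment), `config_hash`, `summary`.
#' @export
run_sweep <- function(m, cs, grid, cfg = solver_config(),
                      det = spike_detector_config(), mode = "ideal",
                      tau_i = 50, max_cells = NULL, outdir = NULL, init = NULL) {
  pairs <- grid_sequences(m, grid, mode = mode, tau_i = tau_i)
  if (!is.null(max_cells)) pairs <- pairs[seq_len(min(max_cells, length(pairs)))]
  if (is.null(init)) init <- init_state(m, cs, cfg)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    s_in <- .spiked(m, cs, pr$in_train, cfg, det, init)
    s_out <- .spiked(m, cs, pr$out_train, cfg, det, init)
    rows[[i]] <- data.frame(n_pulses = pr$n_pulses, interval_ms = pr$interval,
                            weight_nA = pr$weight, spiked_in = s_in,
                            spiked_out = s_out, class = classify(s_in, s_out))
  }
  res <- do.call(rbind, rows)
  ct <- m$compartments$ctype[match(grid$start_id, m$compartments$id)]
  attr(res, "ctype") <- ct
  hash <- .config_hash(list(grid = unclass(grid), cfg = unclass(cfg),
                            det = unclass(det), mode = mode, tau_i = tau_i,
                            max_cells = max_cells))
  attr(res, "config_hash") <- hash
  summary <- list(
    start_id = grid$start_id, ctype = ct, n_rows = nrow(res),
    class_counts = as.list(table(factor(res$class, levels = .response_classes))),
    discriminated_ratio = discriminated_ratio(res),
    config_hash = hash, pcseq_version = .pkg_version())
  attr(res, "summary") <- summary
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res, file.path(outdir, "sweep.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "sweep_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Scan a calcium channel's inactivation time constant
#'
#' Multiplies the inactivation-gate time constant of CaP or CaT by each
#' factor in `f_values` and classifies the IN/OUT pair at each (f, interval)
#' cell, holding n_pulses and weight fixed (defaults 6 pulses, 6.633 nA).
#'
#' @param m a `pc_morphology`.
#' @param cs a `channel_set` (unperturbed; scaling is applied per f).
#' @param channel `"CaP"` or `"CaT"`.
#' @param start_id stimulation start compartment.
#' @param f_values time-constant scale factors (> 0); the study spans
#'   0.1-3.0.
#' @param interval_values inter-pulse intervals, ms.
#' @param n_pulses,weight fixed stimulus parameters.
#' @param cfg,det,mode,tau_i as in [run_sweep()].
#' @param outdir optional output directory; writes `tau_scan.csv`.
#' @return data.frame with columns `f`, `interval_ms`, `spiked_in`,
#'   `spiked_out`, `class` (one row per grid cell, f outer, interval inner).
#' @export
run_tau_scan <- function(m, cs, channel = c("CaT", "CaP"), start_id,
                         f_values = c(0.1, 0.5, 1, 2, 3),
                         interval_values = seq(10, 200, by = 10),
                         n_pulses = 6, weight = 6.633,
                         cfg = solver_config(), det = spike_detector_config(),
                         mode = "ideal", tau_i = 50, outdir = NULL) {
  channel <- match.arg(channel)
  if (any(f_values <= 0)) stop("run_tau_scan: f must be positive")
  grid <- sweep_grid(start_id, n_pulses_values = n_pulses,
                     interval_values = interval_values, weight_values = weight)
  rows <- list()
  for (f in f_values) {
    cs_f <- if (f == 1) cs else scale_tau(cs, channel, f)
    init <- init_state(m, cs_f, cfg)
    pairs <- grid_sequences(m, grid, mode = mode, tau_i = tau_i)
    for (pr in pairs) {
      s_in <- .spiked(m, cs_f, pr$in_train, cfg, det, init)
      s_out <- .spiked(m, cs_f, pr$out_train, cfg, det, init)
      rows[[length(rows) + 1L]] <- data.frame(
        f = f, interval_ms = pr$interval, spiked_in = s_in, spiked_out = s_out,
        class = classify(s_in, s_out))
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "config_hash") <- .config_hash(list(
    channel = channel, start_id = start_id, f = f_values,
    interval = interval_values, n_pulses = n_pulses, weight = weight,
    cfg = unclass(cfg), det = unclass(det), mode = mode, tau_i = tau_i))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res, file.path(outdir, "tau_scan.csv"), row.names = FALSE)
  }
  res
}

#' Run the full learning experiment: identify, learn, retest, diff
#'
#' Executes the study's four-step procedure on a parameter grid: (1) sweep
#' with learning off (`before`); (2) for each responsive sequence, a
#' learning trial pairing the sequence with a delayed CF event; (3) retest
#' both directions with the learned weights, learning off (`after`);
#' (4) report the sequences whose exclusive direction flipped.
#'
#' @param m,cs,grid,cfg,det,mode,tau_i as in [run_sweep()].
#' @param p a [plasticity_params()].
#' @param cf_delay,trial_duration,presentations learning-protocol settings
#'   (`presentations` >= 2 lets the CF trace of one presentation overlap the
#'   next presentation's pulses, activating the LTD term).
#' @param learning_enabled set `FALSE` to verify the null pathway (after
#'   equals before).
#' @param max_cells optional truncation of the grid.
#' @param outdir optional output directory; writes `before.csv`,
#'   `after.csv`, `flipped.csv`.
#' @return List with `before`, `after` (sweep-result data.frames) and
#'   `flipped` (see [reversal_search()]).
#' @export
run_learning_experiment <- function(m, cs, grid, p = plasticity_params(),
                                    cf_delay = 2, trial_duration = 5000,
                                    presentations = 1, learning_enabled = TRUE,
                                    cfg = solver_config(),
                                    det = spike_detector_config(),
                                    mode = "ideal", tau_i = 50,
                                    max_cells = NULL, outdir = NULL) {
  init <- init_state(m, cs, cfg)
  before <- run_sweep(m, cs, grid, cfg, det, mode = mode, tau_i = tau_i,
                      max_cells = max_cells, init = init)
  pairs <- grid_sequences(m, grid, mode = mode, tau_i = tau_i)
  if (!is.null(max_cells)) pairs <- pairs[seq_len(min(max_cells, length(pairs)))]
  if (!learning_enabled) {
    after <- before
    flipped <- list(table = data.frame(), flipped = data.frame())
  } else {
    rev_res <- reversal_search(m, cs, pairs, before, p, cf_delay = cf_delay,
                               trial_duration = trial_duration,
                               presentations = presentations,
                               cfg = cfg, det = det, init = init)
    # "after" table: before rows overwritten by the retested classes
    after <- before
    if (nrow(rev_res$table) > 0) {
      key_b <- paste(after$n_pulses, after$interval_ms, after$weight_nA)
      key_r <- paste(rev_res$table$n_pulses, rev_res$table$interval_ms,
                     rev_res$table$weight_nA)
      hit <- match(key_r, key_b)
      after$class[hit] <- rev_res$table$class_after
      after$spiked_in[hit] <- rev_res$table$class_after %in% c("BOTH", "IN_ONLY")
      after$spiked_out[hit] <- rev_res$table$class_after %in% c("BOTH", "OUT_ONLY")
    }
    flipped <- rev_res
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(before, file.path(outdir, "before.csv"), row.names = FALSE)
    write.csv(after, file.path(outdir, "after.csv"), row.names = FALSE)
    write.csv(flipped$table, file.path(outdir, "flipped.csv"), row.names = FALSE)
  }
  list(before = before, after = after, flipped = flipped$flipped,
       comparison = flipped$table)
}

#' Serialize learned weights as JSON
#'
#' @param w named weight vector (compartment id -> nA).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weights_json <- function(w, path) {
  jsonlite::write_json(as.list(w), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
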