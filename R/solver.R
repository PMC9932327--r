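# R-side surface of the cable-equation solver. Geometry, channel placement
# and gate-kinetics tables are assembled here; time stepping runs in the
# compiled core (src/solver.cpp). Two schemes: the default explicit method
# (forward Euler voltage + exponential-integrator gates) and an implicit
# reference (backward Euler voltage, Hines tree solve) used as numerical
# oracle. Identical inputs give bit-identical traces: there is no randomness
# anywhere in the solver.

#' Solver configuration
#'
#' @param dt time step, ms; defaults to 0.005 ms (explicit) or 0.05 ms
#'   (implicit reference).
#' @param method `"explicit"` or `"implicit_reference"`.
#' @param settle_time pre-stimulus equilibration, ms.
#' @param record_ids compartment ids to record; the soma is always included.
#' @param record_dt recording resolution, ms (snapped to a whole number of
#'   steps).
#' @param v_init initial membrane potential before settling, mV.
#' @return List of class `solver_config`.
#' @export
solver_config <- function(dt = NULL, method = c("explicit", "implicit_reference"),
                          settle_time = 200, record_ids = NULL, record_dt = 0.1,
                          v_init = -68) {
  method <- match.arg(method)
  if (is.null(dt)) dt <- if (method == "explicit") 0.005 else 0.05
  if (!is.numeric(dt) || dt <= 0) stop("solver_config: dt must be > 0")
  if (settle_time < 0) stop("solver_config: settle_time must be >= 0")
  structure(list(dt = dt, method = method, settle_time = settle_time,
                 record_ids = record_ids, record_dt = record_dt,
                 v_init = v_init), class = "solver_config")
}

#' A minimal leak-only channel set (passive membrane)
#'
#' Convenience for passive-cable tests and analytic comparisons; `g_leak = 0`
#' gives a pure-diffusion membrane.
#'
#' @param g_leak leak conductance density, mS/cm^2.
#' @param e_leak leak reversal potential, mV.
#' @return A `channel_set` with only Leak on every compartment type.
#' @export
passive_channel_set <- function(g_leak = 0.033, e_leak = -80.5) {
  gm <- as.list(setNames(rep(g_leak, length(.ctypes)), .ctypes))
  channels <- list(Leak = list(name = "Leak", g_max = gm, e_rev = e_leak,
                               gates = list(), carries_ca = FALSE))
  inventory <- lapply(setNames(.ctypes, .ctypes), function(ct) "Leak")
  structure(list(channels = channels, calcium = calcium_pool(),
                 inventory = inventory, tau_scale = list()),
            class = "channel_set")
}

# Assemble the flat arrays the compiled core consumes. Compartments are
# re-ordered so every parent precedes its children (required by the Hines
# elimination); `ids` maps sim order back to compartment ids.
.build_sim <- function(m, cs) {
  cmp <- m$compartments
  ord <- .topo_order(cmp)
  cmp <- cmp[ord, , drop = FALSE]
  n <- nrow(cmp)
  sim_idx <- setNames(seq_len(n), cmp$id)
  parent <- ifelse(is.na(cmp$parent_id), -1L,
                   as.integer(sim_idx[as.character(cmp$parent_id)]) - 1L)

  r_cm <- cmp$radius * 1e-4
  l_cm <- cmp$length * 1e-4
  area <- 2 * pi * r_cm * l_cm                       # cm^2, lateral
  cap <- m$passive$c_m * area                        # uF
  r_half <- m$passive$r_axial * (l_cm / 2) / (pi * r_cm^2)   # Ohm
  g_ax <- numeric(n)                                 # uA/mV to parent
  for (j in seq_len(n)) {
    if (parent[j] >= 0) g_ax[j] <- 1e3 / (r_half[j] + r_half[parent[j] + 1L])
  }

  # gate tables over a uniform voltage grid; tau pre-scaled by any CaP/CaT
  # inactivation perturbation
  v_grid <- seq(-100, 60, by = 0.05)
  tab_xinf <- list(); tab_tau <- list()
  tab_cadep <- integer(0); tab_kd <- numeric(0); tab_n <- numeric(0)
  tab_key <- character(0)
  gate_specs <- list()
  for (nm in names(cs$channels)) {
    ch <- cs$channels[[nm]]
    for (gi in seq_along(ch$gates)) {
      g <- ch$gates[[gi]]
      key <- paste0(nm, ".", g$name)
      f <- .gate_tau_factor(cs, nm, g$name)
      if (g$ca_dependent) {
        vdesc <- g$xinf; vdesc$form <- "sigmoid"
        xi <- eval_rate(vdesc, v_grid)
        cadep <- 1L; kd <- g$xinf$kd; hn <- g$xinf$n
      } else {
        xi <- steady_state(g, v_grid)
        cadep <- 0L; kd <- 1; hn <- 1
      }
      tau <- time_constant(g, v_grid, ca = 0, f = f)
      tab_xinf[[key]] <- xi; tab_tau[[key]] <- tau
      tab_cadep <- c(tab_cadep, cadep); tab_kd <- c(tab_kd, kd); tab_n <- c(tab_n, hn)
      tab_key <- c(tab_key, key)
      gate_specs[[key]] <- g
    }
  }

  # channel + gate instances, compartment-major
  ch_comp <- integer(0); ch_gbar <- numeric(0); ch_erev <- numeric(0)
  ch_ca <- logical(0); ch_name <- character(0)
  gi_chan <- integer(0); gi_table <- integer(0); gi_exp <- integer(0)
  gi_key <- character(0)
  for (j in seq_len(n)) {
    ct <- cmp$ctype[j]
    for (nm in cs$inventory[[ct]]) {
      ch <- cs$channels[[nm]]
      k <- length(ch_comp) + 1L
      ch_comp <- c(ch_comp, j - 1L)
      ch_gbar <- c(ch_gbar, ch$g_max[[ct]] * area[j])   # mS == uA/mV
      ch_erev <- c(ch_erev, ch$e_rev)
      ch_ca <- c(ch_ca, isTRUE(ch$carries_ca))
      ch_name <- c(ch_name, nm)
      for (g in ch$gates) {
        key <- paste0(nm, ".", g$name)
        gi_chan <- c(gi_chan, k - 1L)
        gi_table <- c(gi_table, match(key, tab_key) - 1L)
        gi_exp <- c(gi_exp, g$exponent)
        gi_key <- c(gi_key, key)
      }
    }
  }

  list(ids = cmp$id, ctype = cmp$ctype, parent = parent, area = area,
       cap = cap, g_ax = g_ax,
       ch_comp = ch_comp, ch_gbar = ch_gbar, ch_erev = ch_erev, ch_ca = ch_ca,
       ch_name = ch_name,
       gi_chan = gi_chan, gi_table = gi_table, gi_exp = gi_exp, gi_key = gi_key,
       tab_xinf = if (length(tab_xinf) > 0) do.call(cbind, tab_xinf) else
         matrix(numeric(0), nrow = length(v_grid), ncol = 0),
       tab_tau = if (length(tab_tau) > 0) do.call(cbind, tab_tau) else
         matrix(numeric(0), nrow = length(v_grid), ncol = 0),
       tab_cadep = tab_cadep, tab_kd = tab_kd, tab_n = tab_n,
       v_min = v_grid[1], v_step = v_grid[2] - v_grid[1],
       gate_specs = gate_specs,
       calcium = cs$calcium,
       soma_id = cmp$id[parent == -1L])
}

# Explicit-stability bound: forward Euler on the membrane equation is stable
# for dt < 2 C / g_total; require dt <= C / g_total (safety factor 2), with
# g_total the axial couplings plus the full open ionic conductance.
.check_stability <- function(sim, dt) {
  n <- length(sim$cap)
  g_tot <- numeric(n)
  for (j in seq_len(n)) {
    if (sim$parent[j] >= 0) {
      g_tot[j] <- g_tot[j] + sim$g_ax[j]
      g_tot[sim$parent[j] + 1L] <- g_tot[sim$parent[j] + 1L] + sim$g_ax[j]
    }
  }
  for (k in seq_along(sim$ch_comp)) {
    g_tot[sim$ch_comp[k] + 1L] <- g_tot[sim$ch_comp[k] + 1L] + sim$ch_gbar[k]
  }
  dt_max <- min(sim$cap / pmax(g_tot, 1e-300))
  if (dt > dt_max) {
    stop(sprintf(paste0("explicit stability bound violated: dt = %g ms but the ",
                        "bound is %g ms; reduce dt or use the implicit reference"),
                 dt, dt_max))
  }
  invisible(dt_max)
}

.run_core <- function(sim, state, cfg, n_steps, pulses = NULL, ext_const = NULL,
                      record_idx = NULL, record_stride = 1L) {
  n <- length(sim$cap)
  if (is.null(ext_const)) ext_const <- numeric(n)
  if (is.null(pulses)) {
    pulses <- list(comp = integer(0), t0 = numeric(0), w = numeric(0),
                   width = 1, mode = 0L, tau_i = 50)
  }
  if (is.null(record_idx)) record_idx <- 0L
  method <- if (cfg$method == "explicit") 0L else 1L
  if (method == 0L) .check_stability(sim, cfg$dt)
  .sim_core(sim$parent, sim$area, sim$cap, sim$g_ax,
            sim$ch_comp, sim$ch_gbar, sim$ch_erev, sim$ch_ca,
            sim$gi_chan, sim$gi_table, sim$gi_exp,
            sim$tab_xinf, sim$tab_tau, sim$v_min, sim$v_step,
            sim$tab_cadep, sim$tab_kd, sim$tab_n,
            sim$calcium$ca_rest, sim$calcium$tau_ca, sim$calcium$phi,
            pulses$comp, pulses$t0, pulses$w,
            pulses$width, pulses$mode, pulses$tau_i,
            ext_const,
            cfg$dt, as.integer(n_steps), state$t, method,
            as.integer(record_idx), as.integer(record_stride),
            state$v, state$gates, state$ca)
}

#' Initialize and settle the simulation state
#'
#' Sets every compartment to the configured initial potential, every gate to
#' its steady state at that potential, and calcium to rest, then integrates
#' `settle_time` ms of zero-input dynamics so the model relaxes to its true
#' resting point before any stimulus. The model has no spontaneous spiking;
#' after settling the state is effectively stationary.
#'
#' @param m a `pc_morphology`.
#' @param cs a `channel_set`.
#' @param cfg a [solver_config()].
#' @return List of class `sim_state` with `v`, `gates`, `ca` (in simulation
#'   order; `ids` gives compartment ids), and `t` (ms, reset to 0 after
#'   settling).
#' @export
init_state <- function(m, cs, cfg = solver_config()) {
  sim <- .build_sim(m, cs)
  n <- length(sim$cap)
  v0 <- rep(cfg$v_init, n)
  ca0 <- rep(sim$calcium$ca_rest, n)
  gates0 <- vapply(seq_along(sim$gi_chan), function(i) {
    g <- sim$gate_specs[[sim$gi_key[i]]]
    comp <- sim$ch_comp[sim$gi_chan[i] + 1L] + 1L
    steady_state(g, v0[comp], ca0[comp])
  }, numeric(1))
  if (length(gates0) == 0) gates0 <- numeric(0)
  if (any(!is.finite(gates0))) stop("init_state: non-finite gate steady state")
  state <- list(v = v0, gates = gates0, ca = ca0, t = 0, ids = sim$ids)
  class(state) <- "sim_state"
  if (cfg$settle_time > 0) {
    n_steps <- ceiling(cfg$settle_time / cfg$dt)
    out <- .run_core(sim, state, cfg, n_steps)
    state$v <- out$v; state$gates <- out$gates; state$ca <- out$ca
    state$t <- 0
  }
  state
}

#' Per-compartment axial current density
#'
#' The tree generalization of the cable equation's second spatial
#' difference: for compartment j, the sum over tree neighbors of
#' `g_axial(j, n) * (v_n - v_j)`, normalized by the membrane area of j.
#' On an unbranched uniform chain this reduces exactly to
#' `a/(2 R) * (v_{j+1} - 2 v_j + v_{j-1}) / dx^2`, with sealed (zero-flux)
#' ends.
#'
#' @param m a `pc_morphology`.
#' @param v per-compartment potential, mV, in the row order of
#'   `m$compartments`.
#' @return Current density, uA/cm^2, positive into the compartment, in the
#'   same order.
#' @export
axial_term <- function(m, v) {
  cmp <- m$compartments
  stopifnot(length(v) == nrow(cmp))
  sim <- .build_sim(m, passive_channel_set(g_leak = 0))
  v_sim <- v[match(sim$ids, cmp$id)]
  i_ax <- numeric(length(v_sim))
  for (j in seq_along(v_sim)) {
    p <- sim$parent[j] + 1L
    if (p >= 1) {
      cur <- sim$g_ax[j] * (v_sim[p] - v_sim[j])
      i_ax[j] <- i_ax[j] + cur
      i_ax[p] <- i_ax[p] - cur
    }
  }
  dens <- i_ax / sim$area
  dens[match(cmp$id, sim$ids)]
}

#' Advance the state by one time step
#'
#' @param m a `pc_morphology`.
#' @param cs a `channel_set`.
#' @param state a `sim_state` (see [init_state()]).
#' @param ext_currents per-compartment external current, nA, in `state$ids`
#'   order (recycled scalar allowed).
#' @param cfg a [solver_config()].
#' @return Updated `sim_state`.
#' @export
step <- function(m, cs, state, ext_currents = 0, cfg = solver_config()) {
  sim <- .build_sim(m, cs)
  ext <- rep_len(ext_currents, length(sim$cap))
  out <- .run_core(sim, state, cfg, 1L, ext_const = ext)
  state$v <- out$v; state$gates <- out$gates; state$ca <- out$ca
  state$t <- out$t_end
  state
}

#' Run a stimulation protocol and record somatic/dendritic traces
#'
#' Integrates the model under a pulse schedule (see [schedule()]) from a
#' settled initial state, recording membrane potential at the requested
#' compartments (the soma is always recorded).
#'
#' @param m a `pc_morphology`.
#' @param cs a `channel_set`.
#' @param protocol a data.frame with columns `compartment`, `t_ms`, `w_nA`
#'   (as produced by [schedule()]); attributes `pulse_width`, `mode`
#'   (`"ideal"` or `"ramped"`) and `tau_i` override the defaults. An empty
#'   or `NULL` protocol runs unstimulated.
#' @param cfg a [solver_config()].
#' @param t_stop simulation end time, ms; default last pulse offset + 500 ms.
#' @param init optional pre-settled `sim_state` to start from (the settle
#'   phase is then skipped — settle once, reuse across a sweep).
#' @return List of class `recorded_trace`: `times` (ms) and `v` (matrix,
#'   one column per recorded compartment, named by id).
#' @export
run <- function(m, cs, protocol = NULL, cfg = solver_config(), t_stop = NULL,
                init = NULL) {
  sim <- .build_sim(m, cs)
  state <- if (is.null(init)) init_state(m, cs, cfg) else init
  if (is.null(protocol) || nrow(as.data.frame(protocol)) == 0L) {
    pulses <- NULL
    if (is.null(t_stop)) t_stop <- 500
  } else {
    pr <- as.data.frame(protocol)
    width <- attr(protocol, "pulse_width"); if (is.null(width)) width <- 1
    mode <- attr(protocol, "mode"); if (is.null(mode)) mode <- "ideal"
    tau_i <- attr(protocol, "tau_i"); if (is.null(tau_i)) tau_i <- 50
    comp_idx <- match(pr$compartment, sim$ids) - 1L
    if (anyNA(comp_idx)) stop("run: protocol references unknown compartment id")
    pulses <- list(comp = as.integer(comp_idx), t0 = pr$t_ms, w = pr$w_nA,
                   width = width, mode = if (mode == "ramped") 1L else 0L,
                   tau_i = tau_i)
    if (is.null(t_stop)) t_stop <- max(pr$t_ms) + width + 500
  }
  rec_ids <- unique(c(sim$soma_id, cfg$record_ids))
  rec_idx <- match(rec_ids, sim$ids) - 1L
  if (anyNA(rec_idx)) stop("run: record_ids contain unknown compartment id")
  stride <- max(1L, round(cfg$record_dt / cfg$dt))
  n_steps <- ceiling(t_stop / cfg$dt)
  out <- .run_core(sim, state, cfg, n_steps, pulses = pulses,
                   record_idx = rec_idx, record_stride = stride)
  v <- out$v_rec
  colnames(v) <- as.character(rec_ids)
  structure(list(times = as.numeric(out$times), v = v,
                 final_state = list(v = out$v, gates = out$gates, ca = out$ca,
                                    t = out$t_end, ids = sim$ids)),
            class = "recorded_trace")
}

#' @export
print.recorded_trace <- function(x, ...) {
  cat("recorded_trace:", length(x$times), "samples,",
      ncol(x$v), "compartment(s), t in [",
      min(x$times), ",", max(x$times), "] ms\n")
  invisible(x)
}

#' Write / read a recorded trace as CSV
#'
#' Long format: `time_ms, compartment, v_mV`.
#'
#' @param tr a `recorded_trace`.
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `recorded_trace`.
#' @export
write_trace_csv <- function(tr, path) {
  long <- data.frame(
    time_ms = rep(tr$times, ncol(tr$v)),
    compartment = rep(as.integer(colnames(tr$v)), each = length(tr$times)),
    v_mV = as.vector(tr$v))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  long <- read.csv(path)
  ids <- sort(unique(long$compartment))
  times <- sort(unique(long$time_ms))
  v <- vapply(ids, function(id) long$v_mV[long$compartment == id], numeric(length(times)))
  v <- matrix(v, ncol = length(ids), dimnames = list(NULL, as.character(ids)))
  structure(list(times = times, v = v), class = "recorded_trace")
}
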