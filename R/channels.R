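# Hodgkin-Huxley-type channel kinetics. Each channel carries up to two gates
# (activation m with exponent q, inactivation h with exponent r). Five
# channels (NaF, NaP, CaP, CaT, KA) use alpha-beta kinetics,
#   x_inf = alpha/(alpha+beta),  tau_x = 1/(alpha+beta);
# all others define x_inf and tau_x directly. The CaP/CaT inactivation time
# constant can be scaled by a factor f (the tau-perturbation experiments).

.alpha_beta_channels <- c("NaF", "NaP", "CaP", "CaT", "KA")
.channel_names <- c("Leak", "NaF", "NaP", "CaP", "CaT", "Kh1", "Kh2",
                    "Kdr", "KM", "KA", "KC", "K2")

#' Gate steady-state value
#'
#' For alpha-beta kinetics returns `alpha/(alpha+beta)`; for direct kinetics
#' evaluates the stored steady-state function. Result is clipped to `[0, 1]`.
#'
#' @param g a gate spec (element of a channel's `gates` list).
#' @param v membrane potential, mV (vectorized).
#' @param ca submembrane calcium, uM (only calcium-dependent gates use it).
#' @return Dimensionless value(s) in `[0, 1]`.
#' @export
steady_state <- function(g, v, ca = 0) {
  if (identical(g$kinetics, "alpha_beta")) {
    a <- eval_rate(g$alpha, v, ca)
    b <- eval_rate(g$beta, v, ca)
    if (any(a + b <= 0)) stop("steady_state: alpha + beta <= 0 in operating range")
    pmin(pmax(a / (a + b), 0), 1)
  } else {
    pmin(pmax(eval_rate(g$xinf, v, ca), 0), 1)
  }
}

#' Gate time constant
#'
#' For alpha-beta kinetics returns `1/(alpha+beta)`; for direct kinetics
#' evaluates the stored time-constant function. The result is multiplied by
#' the perturbation factor `f` (exactly `f`-homogeneous).
#'
#' @inheritParams steady_state
#' @param f dimensionless time-constant scale factor (> 0).
#' @return Time constant(s), ms.
#' @export
time_constant <- function(g, v, ca = 0, f = 1) {
  if (!is.numeric(f) || f <= 0) stop("time_constant: f must be > 0")
  tau <- if (identical(g$kinetics, "alpha_beta")) {
    a <- eval_rate(g$alpha, v, ca)
    b <- eval_rate(g$beta, v, ca)
    1 / (a + b)
  } else {
    eval_rate(g$tau, v, ca)
  }
  if (any(tau <= 0)) stop("time_constant: tau must be positive on the operating range")
  f * tau
}

#' Ionic current density of one channel
#'
#' `g_max * m^q * h^r * (v - E_rev)`; a channel without gates (Leak)
#' contributes its full conductance.
#'
#' @param ch a channel spec (one entry of a [channel_set()]).
#' @param gate_values numeric vector of current gate values, one per gate,
#'   in gate order; each in `[0, 1]`.
#' @param v membrane potential, mV.
#' @param g_max conductance density, mS/cm^2; defaults to the first density
#'   stored in the spec (densities are per compartment type).
#' @return Current density, uA/cm^2 (positive = outward).
#' @export
channel_current <- function(ch, gate_values, v, g_max = NULL) {
  if (is.null(g_max)) g_max <- ch$g_max[[1]]
  open <- 1
  if (length(ch$gates) > 0) {
    stopifnot(length(gate_values) == length(ch$gates))
    for (i in seq_along(ch$gates)) {
      x <- gate_values[[i]]
      if (any(x < 0 | x > 1)) stop("channel_current: gate values must lie in [0, 1]")
      open <- open * x^ch$gates[[i]]$exponent
    }
  }
  g_max * open * (v - ch$e_rev)
}

#' Advance a gate one time step (exponential integrator)
#'
#' Exact for fixed voltage: `x' = x_inf + (x - x_inf) * exp(-dt / tau_x)`.
#'
#' @inheritParams time_constant
#' @param x current gate value.
#' @param dt time step, ms (> 0).
#' @return Updated gate value in `[0, 1]`.
#' @export
step_gate <- function(x, g, v, ca = 0, f = 1, dt) {
  stopifnot(dt > 0)
  xi <- steady_state(g, v, ca)
  tau <- time_constant(g, v, ca, f)
  out <- xi + (x - xi) * exp(-dt / tau)
  pmin(pmax(out, 0), 1)
}

#' Submembrane calcium pool
#'
#' First-order shell model under the membrane: calcium-carrying channel
#' current feeds the shell, and the excess over the resting concentration
#' decays with time constant `tau_ca`. The influx scale derives from the
#' shell depth and the Faraday constant (two charges per ion).
#'
#' @param ca_rest resting concentration, uM.
#' @param shell_depth shell thickness, um.
#' @param tau_ca decay time constant, ms.
#' @return List of class `ca_pool` with the parameters, the derived influx
#'   scale `phi` (uM cm^2 / (uA ms)), and state `ca` (uM).
#' @export
calcium_pool <- function(ca_rest = 0.04, shell_depth = 0.2, tau_ca = 50) {
  stopifnot(ca_rest >= 0, shell_depth > 0, tau_ca > 0)
  faraday <- 96485.33212           # C/mol
  d_cm <- shell_depth * 1e-4
  # uA/cm^2 -> uM/ms in a shell of depth d: 1/(2 F d) with the unit factors
  # (1e-6 A/uA) * (1e9 uM per mol/cm^3) * (1e-3 s/ms) collapsing to 1.
  phi <- 1 / (2 * faraday * d_cm)
  structure(list(ca = ca_rest, ca_rest = ca_rest, shell_depth = shell_depth,
                 tau_ca = tau_ca, phi = phi), class = "ca_pool")
}

#' Advance the calcium pool one time step
#'
#' `d[Ca]/dt = -phi * i_ca - ([Ca] - ca_rest)/tau_ca`, advanced with the
#' exponential integrator (exact for fixed current); inward calcium current
#' (`i_ca < 0`) raises `[Ca]`. The concentration is floored at 0.
#'
#' @param p a [calcium_pool()].
#' @param i_ca summed calcium-channel current density, uA/cm^2.
#' @param dt time step, ms (> 0).
#' @return Updated `ca_pool`.
#' @export
step_calcium <- function(p, i_ca, dt) {
  stopifnot(dt > 0)
  target <- p$ca_rest - p$phi * i_ca * p$tau_ca    # fixed-current steady state
  p$ca <- max(target + (p$ca - target) * exp(-dt / p$tau_ca), 0)
  p
}

#' Load a channel set from a JSON parameter file
#'
#' The file declares every channel's reversal potential, gates (functional
#' forms + coefficients), and per-compartment-type conductance densities,
#' plus the calcium-pool constants. The packaged default
#' (`system.file("extdata", "channels_purkinje.json", package = "pcseq")`)
#' carries the Purkinje-cell inventory: soma Leak/NaF/NaP/CaT/Kh1/Kh2/Kdr/
#' KM/KA; main dendrite Leak/CaP/CaT/Kdr/KM/KA/KC/K2; smooth and spiny
#' dendrites Leak/CaP/CaT/KM/KC/K2.
#'
#' @param path path to the JSON file; default the packaged parameter file.
#' @return An object of class `channel_set`: list with `channels` (named
#'   channel specs), `calcium` (pool constants), and `inventory` (ctype ->
#'   channel names, derived from which ctypes carry a density).
#' @export
load_channel_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "channels_purkinje.json", package = "pcseq")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$channels)) stop("load_channel_set: file has no 'channels' block")
  channels <- list()
  for (nm in names(obj$channels)) {
    if (!nm %in% .channel_names) stop("load_channel_set: unknown channel '", nm, "'")
    raw <- obj$channels[[nm]]
    gm <- lapply(raw$g_max, as.numeric)
    if (any(unlist(gm) < 0)) stop("load_channel_set: negative g_max for ", nm)
    bad_ct <- setdiff(names(gm), .ctypes)
    if (length(bad_ct) > 0) stop("load_channel_set: unknown ctype '", bad_ct[1], "' for ", nm)
    gates <- lapply(raw$gates, function(g) {
      g$exponent <- as.integer(g$exponent)
      if (g$exponent < 0) stop("load_channel_set: negative gate exponent in ", nm)
      if (!g$kinetics %in% c("alpha_beta", "direct")) {
        stop("load_channel_set: gate kinetics must be alpha_beta or direct (", nm, ")")
      }
      for (d in intersect(c("alpha", "beta", "xinf", "tau"), names(g))) {
        if (!g[[d]]$form %in% .rate_forms) {
          stop("load_channel_set: unknown functional form '", g[[d]]$form, "' in ", nm)
        }
      }
      g$ca_dependent <- isTRUE(g$ca_dependent)
      g
    })
    ab <- nm %in% .alpha_beta_channels
    for (g in gates) {
      if (ab && !identical(g$kinetics, "alpha_beta")) {
        stop("load_channel_set: ", nm, " must use alpha-beta kinetics")
      }
      if (!ab && !identical(g$kinetics, "direct")) {
        stop("load_channel_set: ", nm, " must use direct kinetics")
      }
    }
    channels[[nm]] <- list(name = nm, g_max = gm, e_rev = as.numeric(raw$e_rev),
                           gates = gates, carries_ca = isTRUE(raw$carries_ca))
  }
  inventory <- lapply(setNames(.ctypes, .ctypes), function(ct) {
    names(channels)[vapply(channels, function(ch) ct %in% names(ch$g_max), logical(1))]
  })
  for (ct in .ctypes) {
    if (!"Leak" %in% inventory[[ct]]) {
      stop("load_channel_set: compartment type '", ct, "' has no Leak channel")
    }
  }
  cal <- obj$calcium
  pool <- calcium_pool(ca_rest = as.numeric(cal$ca_rest),
                       shell_depth = as.numeric(cal$shell_depth),
                       tau_ca = as.numeric(cal$tau_ca))
  structure(list(channels = channels, calcium = pool, inventory = inventory,
                 tau_scale = list()), class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat("channel_set:", length(x$channels), "channels\n")
  for (ct in names(x$inventory)) {
    cat(" ", ct, ":", paste(x$inventory[[ct]], collapse = ", "), "\n")
  }
  if (length(x$tau_scale) > 0) {
    for (nm in names(x$tau_scale)) {
      cat("  tau scale:", nm, "h-gate x", x$tau_scale[[nm]], "\n")
    }
  }
  invisible(x)
}

#' Scale the inactivation time constant of a calcium channel
#'
#' Multiplies the inactivation (h) gate time constant of CaP or CaT by a
#' factor `f` — the perturbation used to probe which calcium channel's
#' inactivation kinetics carry the temporal memory for sequence
#' discrimination. Only the h gates of CaP and CaT may be scaled.
#'
#' @param cs a `channel_set`.
#' @param channel `"CaP"` or `"CaT"`.
#' @param f positive scale factor (the unperturbed model has `f = 1`).
#' @return A `channel_set` with the scaling recorded (applied at simulation
#'   time and by [time_constant()] via the solver's gate tables).
#' @export
scale_tau <- function(cs, channel, f) {
  stopifnot(inherits(cs, "channel_set"))
  if (!channel %in% c("CaP", "CaT")) {
    stop("scale_tau: tau scaling applies only to CaP or CaT")
  }
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f <= 0) {
    stop("scale_tau: f must be a positive finite number")
  }
  if (!channel %in% names(cs$channels)) stop("scale_tau: channel ", channel, " not in set")
  has_h <- any(vapply(cs$channels[[channel]]$gates, function(g) g$name == "h", logical(1)))
  if (!has_h) stop("scale_tau: channel ", channel, " has no inactivation gate")
  cs$tau_scale[[channel]] <- f
  cs
}

# effective tau multiplier for a (channel, gate) pair under the set's scaling
.gate_tau_factor <- function(cs, channel_name, gate_name) {
  if (gate_name == "h" && channel_name %in% names(cs$tau_scale)) {
    cs$tau_scale[[channel_name]]
  } else 1
}
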