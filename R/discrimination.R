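# Spike detection on somatic traces, four-way IN/OUT response
# classification, and the discriminated-sequence ratio.

.response_classes <- c("BOTH", "IN_ONLY", "OUT_ONLY", "NEITHER")

#' Spike detector configuration
#'
#' The classification only needs spiking vs non-spiking; a spike is an
#' upward crossing of `threshold`, with successive detections at least
#' `min_separation` ms apart. The defaults (0 mV, 2 ms) are unambiguous for
#' Hodgkin-Huxley-type somatic spikes.
#'
#' @param threshold crossing threshold, mV.
#' @param min_separation refractory separation between detections, ms (> 0).
#' @param grace post-stimulus grace window, ms: a response counts if a spike
#'   falls in `[first pulse onset, last pulse offset + grace]`.
#' @return List of class `spike_detector_config`.
#' @export
spike_detector_config <- function(threshold = 0, min_separation = 2, grace = 500) {
  if (min_separation <= 0) stop("spike_detector_config: min_separation must be > 0")
  structure(list(threshold = threshold, min_separation = min_separation,
                 grace = grace), class = "spike_detector_config")
}

#' Detect spikes in a recorded trace
#'
#' @param tr a `recorded_trace` (see [run()]) or a numeric voltage vector
#'   (then `times` must be given).
#' @param cfg a [spike_detector_config()].
#' @param compartment column to analyze (id as character or column index);
#'   default the first recorded column (the soma).
#' @param times sample times, ms (only when `tr` is a bare vector).
#' @return Numeric vector of spike times, ms.
#' @export
detect_spikes <- function(tr, cfg = spike_detector_config(), compartment = 1,
                          times = NULL) {
  if (inherits(tr, "recorded_trace")) {
    v <- tr$v[, compartment]
    times <- tr$times
  } else {
    v <- as.numeric(tr)
    if (is.null(times)) stop("detect_spikes: times required for a bare voltage vector")
  }
  if (length(v) == 0) stop("detect_spikes: empty trace")
  up <- which(v[-1] > cfg$threshold & v[-length(v)] <= cfg$threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  t_up <- times[up]
  keep <- numeric(0)
  last <- -Inf
  for (t in t_up) {
    if (t - last >= cfg$min_separation) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' Classify an IN/OUT response pair
#'
#' @param spiked_in,spiked_out logical: did the soma spike under the IN /
#'   OUT presentation of the same triplet?
#' @return One of `"BOTH"`, `"IN_ONLY"`, `"OUT_ONLY"`, `"NEITHER"`
#'   (vectorized).
#' @export
classify <- function(spiked_in, spiked_out) {
  stopifnot(length(spiked_in) == length(spiked_out))
  ifelse(spiked_in & spiked_out, "BOTH",
         ifelse(spiked_in, "IN_ONLY",
                ifelse(spiked_out, "OUT_ONLY", "NEITHER")))
}

#' Discriminated-sequence ratio
#'
#' Fraction of parameter triplets whose soma response distinguishes the two
#' directions: `(IN_ONLY + OUT_ONLY) / total`.
#'
#' @param r a sweep result: data.frame with a `class` column (see
#'   [run_sweep()]).
#' @return Fraction in `[0, 1]`.
#' @export
discriminated_ratio <- function(r) {
  cl <- if (is.data.frame(r)) r$class else r
  if (length(cl) == 0) stop("discriminated_ratio: empty sweep result")
  if (!all(cl %in% .response_classes)) stop("discriminated_ratio: unknown class value")
  sum(cl %in% c("IN_ONLY", "OUT_ONLY")) / length(cl)
}

#' Summarize discrimination across sweep cubes by dendrite type
#'
#' Unweighted mean of per-cube discriminated ratios within each compartment
#' type (cube sizes may differ, so each cube counts once).
#'
#' @param results list of sweep results; each must carry the start
#'   compartment's ctype in `attr(x, "ctype")` or a `ctype` column.
#' @return List with `per_cube` (data.frame: ctype, ratio) and `mean_ratio`
#'   (named numeric, one entry per ctype present).
#' @export
summarize_cubes <- function(results) {
  stopifnot(length(results) >= 1)
  per_cube <- do.call(rbind, lapply(results, function(r) {
    ct <- attr(r, "ctype")
    if (is.null(ct) && "ctype" %in% names(r)) ct <- r$ctype[1]
    if (is.null(ct)) stop("summarize_cubes: result without a ctype")
    data.frame(ctype = ct, ratio = discriminated_ratio(r))
  }))
  means <- tapply(per_cube$ratio, per_cube$ctype, mean)
  list(per_cube = per_cube, mean_ratio = setNames(as.numeric(means), names(means)))
}
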