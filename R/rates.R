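# Rate functions are data, not code: each gate's kinetics is a named
# functional form plus coefficients, loaded from the channel parameter file.
# Units: v in mV, rates in 1/ms, time constants in ms, calcium in uM.
#
# Forms
#   exp          a * exp((v - v0)/k)
#   sigmoid      b + a / (1 + exp(-(v - v0)/k))         (k < 0 -> falling)
#   linoid       a * (v - v0) / (1 - exp(-(v - v0)/k))
#   const        a
#   bell         base + amp / (exp((v - v0)/k1) + exp(-(v - v0)/k2))
#   hill_sigmoid (ca^n / (ca^n + kd^n)) * sigmoid(v)    (ca-dependent x_inf)

.rate_forms <- c("exp", "sigmoid", "linoid", "const", "bell", "hill_sigmoid")

#' Evaluate a rate-function descriptor
#'
#' @param desc list with element `form` (one of `exp`, `sigmoid`, `linoid`,
#'   `const`, `bell`, `hill_sigmoid`) and the form's coefficients.
#' @param v membrane potential, mV (vectorized).
#' @param ca submembrane calcium, uM (used by `hill_sigmoid` only).
#' @return Numeric vector of rate (1/ms) or time-constant (ms) values.
#' @export
eval_rate <- function(desc, v, ca = 0) {
  if (is.null(desc$form) || !desc$form %in% .rate_forms) {
    stop("eval_rate: unknown functional form '", desc$form, "'")
  }
  g <- function(nm, default = NULL) {
    x <- desc[[nm]]
    if (is.null(x)) {
      if (is.null(default)) stop("eval_rate: form '", desc$form, "' needs coefficient '", nm, "'")
      default
    } else x
  }
  switch(desc$form,
    exp = g("a") * exp(pmin((v - g("v0")) / g("k"), 700)),
    sigmoid = g("b", 0) + g("a") / (1 + exp(pmin(-(v - g("v0")) / g("k"), 700))),
    linoid = {
      u <- (v - g("v0")) / g("k")
      out <- ifelse(abs(u) < 1e-7, g("a") * g("k") * (1 + u / 2),
                    g("a") * (v - g("v0")) / (1 - exp(-u)))
      out
    },
    const = rep_len(g("a"), length(v)),
    bell = g("base", 0) + g("amp") /
      (exp((v - g("v0")) / g("k1")) + exp(-(v - g("v0")) / g("k2"))),
    hill_sigmoid = {
      can <- pmax(ca, 0)^g("n")
      (can / (can + g("kd")^g("n"))) *
        (g("b", 0) + g("a") / (1 + exp(pmin(-(v - g("v0")) / g("k"), 700))))
    }
  )
}
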