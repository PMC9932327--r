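# Fixtures are built in code at test time; nothing is downloaded.

# 3-point linear SWC: soma -> two dendrite points, 20 um spacing
write_swc_linear3 <- function(path = tempfile(fileext = ".swc")) {
  writeLines(c(
    "# linear 3-point fixture",
    "1 1 0 0 0 10 -1",
    "2 3 20 0 0 1 1",
    "3 3 40 0 0 1 2"), path)
  path
}

# SWC with a parent cycle between points 2 and 3
write_swc_cycle <- function(path = tempfile(fileext = ".swc")) {
  writeLines(c(
    "1 1 0 0 0 10 -1",
    "2 3 20 0 0 1 3",
    "3 3 40 0 0 1 2"), path)
  path
}

# minimal GENESIS-style .p: soma plus one dendrite compartment
write_p_two_line <- function(path = tempfile(fileext = ".p")) {
  writeLines(c(
    "// two-line fixture",
    "*relative",
    "soma none 20 0 0 20",
    "main1 soma 40 0 0 6"), path)
  path
}

# small linear morphology: soma, 2 main, 3 smooth, 5 spiny (11 compartments)
linear11 <- function() {
  generate_reduced(n_main = 2, n_smooth = 3, n_spiny = 5, branching = 1, seed = 7)
}

# the packaged reduced tree used by the qualitative experiments
reduced_tree <- function() generate_reduced()

# an alpha-beta gate with constant rates, for closed-form checks
const_gate <- function(alpha, beta, exponent = 1) {
  list(name = "m", exponent = exponent, kinetics = "alpha_beta",
       alpha = list(form = "const", a = alpha),
       beta = list(form = "const", a = beta),
       ca_dependent = FALSE)
}

# a direct-kinetics gate with constant tau and sigmoid steady state
direct_gate <- function(v0 = -50, k = 5, tau = 10) {
  list(name = "m", exponent = 1, kinetics = "direct",
       xinf = list(form = "sigmoid", a = 1, v0 = v0, k = k),
       tau = list(form = "const", a = tau),
       ca_dependent = FALSE)
}
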