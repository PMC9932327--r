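test_that("steady state follows alpha/(alpha+beta) and clips to [0,1]", {
  g <- const_gate(alpha = 2, beta = 2)
  expect_equal(steady_state(g, -60), 0.5)
  g0 <- const_gate(alpha = 0, beta = 3)
  expect_equal(steady_state(g0, -60), 0)
  gb <- const_gate(alpha = 0, beta = 0)
  expect_error(steady_state(gb, -60), "alpha \\+ beta")
})

test_that("packaged kinetics match independent evaluation of the stored forms", {
  # brute-force oracle: read the JSON coefficients directly and evaluate the
  # functional forms with plain arithmetic, independent of eval_rate()
  path <- system.file("extdata", "channels_purkinje.json", package = "pcseq")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  brute <- function(d, v) {
    switch(d$form,
      exp = d$a * exp((v - d$v0) / d$k),
      sigmoid = (if (is.null(d$b)) 0 else d$b) + d$a / (1 + exp(-(v - d$v0) / d$k)),
      const = d$a,
      bell = (if (is.null(d$base)) 0 else d$base) +
        d$amp / (exp((v - d$v0) / d$k1) + exp(-(v - d$v0) / d$k2)),
      hill_sigmoid = d$a / (1 + exp(-(v - d$v0) / d$k)),  # voltage part only
      stop("unknown form"))
  }
  cs <- load_channel_set()
  for (nm in names(cs$channels)) {
    ch <- cs$channels[[nm]]
    raw_gates <- raw$channels[[nm]]$gates
    for (i in seq_along(ch$gates)) {
      g <- ch$gates[[i]]
      rg <- raw_gates[[i]]
      for (v in c(-60, -40, -20)) {
        if (identical(g$kinetics, "alpha_beta")) {
          a <- brute(rg$alpha, v); b <- brute(rg$beta, v)
          expect_equal(steady_state(g, v), min(max(a / (a + b), 0), 1),
                       tolerance = 1e-12,
                       label = paste(nm, g$name, "xinf at", v))
          expect_equal(time_constant(g, v), 1 / (a + b), tolerance = 1e-12,
                       label = paste(nm, g$name, "tau at", v))
        } else if (!g$ca_dependent) {
          expect_equal(steady_state(g, v), min(max(brute(rg$xinf, v), 0), 1),
                       tolerance = 1e-12, label = paste(nm, g$name, "xinf", v))
          expect_equal(time_constant(g, v), brute(rg$tau, v), tolerance = 1e-12,
                       label = paste(nm, g$name, "tau", v))
        } else {
          ca <- 2.5
          hillv <- ca^rg$xinf$n / (ca^rg$xinf$n + rg$xinf$kd^rg$xinf$n)
          expect_equal(steady_state(g, v, ca = ca),
                       min(max(hillv * brute(rg$xinf, v), 0), 1),
                       tolerance = 1e-12, label = paste(nm, g$name, "ca xinf", v))
        }
      }
    }
  }
})

test_that("time_constant is exactly f-homogeneous and guards its domain", {
  g <- direct_gate(tau = 10)
  expect_equal(time_constant(g, -50, f = 1), 10)
  expect_equal(time_constant(g, -50, f = 2), 2 * time_constant(g, -50, f = 1))
  gab <- const_gate(alpha = 1, beta = 1)
  expect_equal(time_constant(gab, -50), 0.5)
  expect_error(time_constant(g, -50, f = 0), "f must be")
  expect_error(time_constant(g, -50, f = -1), "f must be")
})

test_that("channel_current implements g m^q h^r (v - E)", {
  ch <- list(name = "X", g_max = list(spiny = 10), e_rev = -85,
             gates = list(const_gate(1, 1, exponent = 2)))
  expect_equal(channel_current(ch, 0, v = -20), 0)
  expect_equal(channel_current(ch, 0.7, v = -85), 0)       # reversal
  expect_equal(channel_current(ch, 0.5, v = -65), 10 * 0.25 * 20)
  # linear in g_max
  ch2 <- ch; ch2$g_max$spiny <- 20
  expect_equal(channel_current(ch2, 0.5, v = -65),
               2 * channel_current(ch, 0.5, v = -65))
  # Leak: no gates, full conductance
  leak <- list(name = "Leak", g_max = list(spiny = 0.033), e_rev = -80.5,
               gates = list())
  expect_equal(channel_current(leak, numeric(0), v = -60.5), 0.033 * 20)
})

test_that("gate stepping is the exact exponential integrator at fixed voltage", {
  g <- direct_gate(v0 = -50, k = 5, tau = 10)
  xi <- steady_state(g, -50)       # 0.5
  expect_equal(step_gate(xi, g, -50, dt = 3), xi)          # fixed point
  # dt = tau, x_inf = 0: x' = e^-1
  g0 <- list(name = "m", exponent = 1, kinetics = "direct",
             xinf = list(form = "const", a = 0), tau = list(form = "const", a = 10),
             ca_dependent = FALSE)
  expect_equal(step_gate(1, g0, -50, dt = 10), exp(-1), tolerance = 1e-12)
  # 5 tau convergence from any start
  for (x0 in c(0, 0.3, 1)) {
    x <- x0
    for (i in 1:50) x <- step_gate(x, g, -65, dt = 0.1 * time_constant(g, -65))
    expect_lt(abs(x - steady_state(g, -65)), 0.01)
  }
  # matches the analytic solution of the relaxation ODE for any dt
  dt <- 7.3; x0 <- 0.9
  analytic <- steady_state(g, -60) +
    (x0 - steady_state(g, -60)) * exp(-dt / time_constant(g, -60))
  expect_equal(step_gate(x0, g, -60, dt = dt), analytic, tolerance = 1e-12)
})

test_that("the calcium shell relaxes to its closed-form targets", {
  p <- calcium_pool(ca_rest = 0.04, shell_depth = 0.2, tau_ca = 50)
  # equilibrium
  expect_equal(step_calcium(p, 0, dt = 5)$ca, 0.04)
  # zero current: excess decays to 1/e over tau_ca
  p2 <- p; p2$ca <- 0.08
  out <- step_calcium(p2, 0, dt = 50)
  expect_equal(out$ca - 0.04, 0.04 * exp(-1), tolerance = 1e-12)
  # constant inward current: approach ca_rest + phi*|i|*tau
  p3 <- p
  for (i in 1:200) p3 <- step_calcium(p3, -1, dt = 50)
  expect_equal(p3$ca, 0.04 + p$phi * 1 * 50, tolerance = 1e-9)
  # floored at zero under an outward (clearing) current
  p4 <- p
  p4 <- step_calcium(p4, 1e6, dt = 5000)
  expect_gte(p4$ca, 0)
})

test_that("the packaged channel file reproduces the per-type inventories", {
  cs <- load_channel_set()
  expect_setequal(cs$inventory$spiny, c("Leak", "CaP", "CaT", "KM", "KC", "K2"))
  expect_setequal(cs$inventory$smooth, c("Leak", "CaP", "CaT", "KM", "KC", "K2"))
  expect_setequal(cs$inventory$main,
                  c("Leak", "CaP", "CaT", "Kdr", "KM", "KA", "KC", "K2"))
  expect_true("NaF" %in% cs$inventory$soma)
  expect_false("CaP" %in% cs$inventory$soma)
  expect_setequal(cs$inventory$soma,
                  c("Leak", "NaF", "NaP", "CaT", "Kh1", "Kh2", "Kdr", "KM", "KA"))
})

test_that("schema violations in a channel file are rejected", {
  path <- system.file("extdata", "channels_purkinje.json", package = "pcseq")
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  bad <- obj
  bad$channels$NaF$g_max$soma <- -5
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_channel_set(f), "negative g_max")

  bad2 <- obj
  bad2$channels$KM$gates[[1]]$xinf$form <- "mystery"
  jsonlite::write_json(bad2, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_channel_set(f), "unknown functional form")

  bad3 <- obj
  bad3$channels$Leak$g_max$spiny <- NULL
  jsonlite::write_json(bad3, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_channel_set(f), "no Leak")
})

test_that("tau scaling is restricted to CaP/CaT inactivation", {
  cs <- load_channel_set()
  expect_error(scale_tau(cs, "KM", 2), "only to CaP or CaT")
  expect_error(scale_tau(cs, "CaT", 0), "positive")
  expect_error(scale_tau(cs, "CaT", -0.5), "positive")
  cs2 <- scale_tau(cs, "CaT", 0.1)
  expect_equal(cs2$tau_scale$CaT, 0.1)
  # the h gate's effective tau scales by exactly f; m gates are untouched
  h <- cs$channels$CaT$gates[[2]]
  m_gate <- cs$channels$CaT$gates[[1]]
  f <- pcseq:::.gate_tau_factor(cs2, "CaT", "h")
  expect_equal(f, 0.1)
  expect_equal(pcseq:::.gate_tau_factor(cs2, "CaT", "m"), 1)
  expect_equal(time_constant(h, -60, f = f), 0.1 * time_constant(h, -60))
})

test_that("gate values stay within [0,1] along arbitrary voltage excursions", {
  cs <- load_channel_set()
  set.seed(42)
  vs <- runif(200, -100, 60)
  for (nm in c("NaF", "CaT", "KC", "Kdr")) {
    for (g in cs$channels[[nm]]$gates) {
      x <- 0.5
      for (v in vs) {
        x <- step_gate(x, g, v, ca = runif(1, 0, 10), dt = 0.1)
        expect_true(x >= 0 && x <= 1)
      }
    }
  }
})
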