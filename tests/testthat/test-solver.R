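# Numerical correctness of the cable integrator: analytic limits,
# conservation, and the explicit-vs-implicit cross-solver oracle.

uniform_chain <- function(n, radius = 1, len = 20) {
  cmp <- data.frame(id = seq_len(n),
                    parent_id = c(NA, seq_len(n - 1)),
                    ctype = c("soma", rep("spiny", n - 1)),
                    length = len, radius = radius)
  morphology(cmp)
}

active10 <- function() {
  generate_reduced(n_main = 2, n_smooth = 3, n_spiny = 4, branching = 1,
                   seed = 5)
}

test_that("axial term reduces to the sealed-end second difference on a chain", {
  m <- uniform_chain(3)
  expect_equal(axial_term(m, c(-65, -65, -65)), rep(0, 3))   # constant field

  v <- c(0, 1, 0)
  got <- axial_term(m, v)
  a_cm <- 1e-4; dx_cm <- 20e-4; R <- m$passive$r_axial
  coef <- 1e3 * a_cm / (2 * R * dx_cm^2)       # uA/cm^2 per mV
  expect_equal(got, coef * c(1, -2, 1), tolerance = 1e-12)
})

test_that("axial flux is antisymmetric: total charge flux sums to zero", {
  m <- reduced_tree()
  set.seed(9)
  for (rep in 1:5) {
    v <- runif(nrow(m$compartments), -90, 0)
    dens <- axial_term(m, v)
    r_cm <- m$compartments$radius * 1e-4
    l_cm <- m$compartments$length * 1e-4
    area <- 2 * pi * r_cm * l_cm
    expect_equal(sum(dens * area), 0, tolerance = 1e-12 * sum(abs(dens * area)))
  }
})

test_that("a passive membrane settles to the leak reversal and stays there", {
  m <- uniform_chain(5)
  cs <- passive_channel_set()
  cfg <- solver_config(dt = 0.01, settle_time = 1000)
  st <- init_state(m, cs, cfg)
  expect_equal(st$v, rep(-80.5, 5), tolerance = 1e-6)
  tr <- run(m, cs, NULL, cfg = solver_config(dt = 0.01, settle_time = 0),
            t_stop = 100, init = st)
  expect_lt(max(abs(tr$v - (-80.5))), 1e-6)
})

test_that("identical models settle to identical states (determinism)", {
  m <- active10()
  cs <- load_channel_set()
  cfg <- solver_config(settle_time = 100)
  st1 <- init_state(m, cs, cfg)
  st2 <- init_state(m, cs, cfg)
  expect_identical(st1$v, st2$v)
  expect_identical(st1$gates, st2$gates)
  expect_identical(st1$ca, st2$ca)
})

test_that("pure diffusion conserves area-weighted charge to 1e-9 relative", {
  m <- uniform_chain(8, radius = c(2, 2, 1.5, 1.5, 1, 1, 0.8, 0.8))
  cs <- passive_channel_set(g_leak = 0)        # no leak: diffusion only
  for (method in c("explicit", "implicit_reference")) {
    cfg <- solver_config(method = method, settle_time = 0)
    st <- init_state(m, cs, cfg)
    set.seed(4)
    st$v <- runif(8, -90, 10)
    r_cm <- m$compartments$radius * 1e-4
    area <- 2 * pi * r_cm * (m$compartments$length * 1e-4)
    area_sim <- area[match(st$ids, m$compartments$id)]
    q0 <- sum(area_sim * st$v)
    tr <- run(m, cs, NULL, cfg, t_stop = 50, init = st)
    q1 <- sum(area_sim * tr$final_state$v)
    expect_equal(q1, q0, tolerance = 1e-9)
    # and the profile has genuinely diffused toward the mean
    expect_lt(diff(range(tr$final_state$v)), diff(range(st$v)))
  }
})

test_that("an isopotential compartment follows the closed-form RC response", {
  m1 <- morphology(data.frame(id = 1, parent_id = NA, ctype = "soma",
                              length = 20, radius = 10))
  cs <- passive_channel_set()
  cfg <- solver_config(dt = 0.01, settle_time = 1000)
  st <- init_state(m1, cs, cfg)
  area <- 2 * pi * 10e-4 * 20e-4
  g <- 0.033 * area                    # mS == uA/mV
  I_uA <- 0.05                         # 50 nA
  tau <- m1$passive$c_m * area / g     # ms
  proto <- data.frame(compartment = 1, t_ms = 0, w_nA = 50)
  attr(proto, "pulse_width") <- 5 * tau
  tr <- run(m1, cs, proto, solver_config(dt = 0.01, settle_time = 0),
            t_stop = 5 * tau, init = st)
  v_inf <- -80.5 + I_uA / g
  # at t = tau the response is 1 - e^-1 of the way to v_inf
  v_at <- function(t) unname(tr$v[which.min(abs(tr$times - t)), 1])
  expect_equal((v_at(tau) - (-80.5)) / (v_inf - (-80.5)), 1 - exp(-1),
               tolerance = 2e-3)
  expect_equal(v_at(5 * tau), v_inf + (-80.5 - v_inf) * exp(-5),
               tolerance = 1e-2)
})

test_that("steady-state voltage matches the analytic cosh cable profile", {
  n <- 26
  m <- uniform_chain(n, radius = 0.7, len = 20)
  cs <- passive_channel_set()
  cfg <- solver_config(dt = 0.01, settle_time = 0)
  st <- init_state(m, cs, solver_config(dt = 0.01, settle_time = 100))
  # constant current into the distal tip (compartment n), sealed ends
  proto <- data.frame(compartment = n, t_ms = 0, w_nA = 0.01)
  attr(proto, "pulse_width") <- 600
  tr <- run(m, cs, proto, cfg, t_stop = 600, init = st)
  v_num <- tr$final_state$v[match(m$compartments$id, tr$final_state$ids)]

  a_cm <- 0.7e-4; dx_cm <- 20e-4
  r_m <- (1 / 0.033e-3) / (2 * pi * a_cm)        # Ohm cm (R_m = 1/g_leak)
  r_a <- m$passive$r_axial / (pi * a_cm^2)       # Ohm / cm
  lambda <- sqrt(r_m / r_a)
  ell <- n * dx_cm
  I_uA <- 0.01 * 1e-3
  # x measured from the injected (distal) end, compartment centers;
  # I*r_a*lambda is in uV, hence the 1e-3 to mV
  x <- (seq_len(n) - 0.5) * dx_cm
  v_ana <- -80.5 + 1e-3 * I_uA * r_a * lambda *
    cosh((ell - x) / lambda) / sinh(ell / lambda)
  v_ana <- rev(v_ana)                            # id 1 is the far end
  expect_lt(max(abs(v_num - v_ana)) / (max(v_ana) + 80.5), 0.01)
})

test_that("explicit and implicit solvers agree on an active fixture", {
  m <- active10()
  cs <- load_channel_set()
  cfg_e <- solver_config(method = "explicit", settle_time = 200)
  cfg_i <- solver_config(method = "implicit_reference", dt = 0.01,
                         settle_time = 200)
  st_e <- init_state(m, cs, cfg_e)
  st_i <- init_state(m, cs, cfg_i)
  path <- rev(straight_path(m, max(m$compartments$id), 3, toward_soma = TRUE))
  proto <- schedule(pulse_train(path, "IN", interval = 40, weight = 0.5))
  tr_e <- run(m, cs, proto, cfg_e, t_stop = 500, init = st_e)
  tr_i <- run(m, cs, proto, cfg_i, t_stop = 500, init = st_i)
  expect_equal(tr_e$times, tr_i$times)
  expect_lt(max(abs(tr_e$v[, 1] - tr_i$v[, 1])), 1)
})

test_that("halving the explicit step shrinks the trace difference (order ~1)", {
  m <- active10()
  cs <- load_channel_set()
  path <- rev(straight_path(m, max(m$compartments$id), 3, toward_soma = TRUE))
  proto <- schedule(pulse_train(path, "IN", interval = 30, weight = 0.5))
  trace_at <- function(dt) {
    cfg <- solver_config(dt = dt, settle_time = 100)
    st <- init_state(m, cs, cfg)
    run(m, cs, proto, solver_config(dt = dt, settle_time = 0),
        t_stop = 200, init = st)$v[, 1]
  }
  v1 <- trace_at(0.004)
  v2 <- trace_at(0.002)
  v3 <- trace_at(0.001)
  d12 <- max(abs(v1 - v2))
  d23 <- max(abs(v2 - v3))
  expect_lt(d23, 0.75 * d12)
})

test_that("the stability guard rejects an unstable explicit step", {
  m <- uniform_chain(5)
  cs <- passive_channel_set()
  cfg <- solver_config(dt = 5, settle_time = 10)   # absurdly large step
  expect_error(init_state(m, cs, cfg), "stability bound")
})

test_that("traces are recorded on a uniform, strictly increasing clock", {
  m <- uniform_chain(4)
  cs <- passive_channel_set()
  cfg <- solver_config(dt = 0.01, settle_time = 0, record_dt = 0.5)
  st <- init_state(m, cs, cfg)
  tr <- run(m, cs, NULL, cfg, t_stop = 20, init = st)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(unique(round(diff(tr$times), 9)), 0.5)
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f)
  expect_equal(tr2$times, tr$times)
  expect_equal(unname(tr2$v[, 1]), unname(tr$v[, 1]), tolerance = 1e-6)
})
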