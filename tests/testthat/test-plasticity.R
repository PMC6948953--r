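# Exact propagation of the fast/slow plasticity variables

test_that("pairing relaxation matches the closed form and an independent ODE solver", {
  p <- plasticity_params()
  seg <- segment(60, "on", kc = TRUE)
  s <- propagate_segment(synapse_state(), seg, p)

  # frozen values: 1 - e^-4.3 for the fast DA variable, filtered values from
  # the first-order expression dynamics (verified against deSolve below)
  expect_equal(s$d_fast, 0.9864314, tolerance = 1e-6)
  expect_equal(s$d_slow, 0.7587812, tolerance = 1e-6)
  expect_equal(s$n_fast, 0.6171071, tolerance = 1e-6)
  expect_equal(s$n_slow, 0.0344714, tolerance = 1e-5)

  oracle <- ode_oracle(synapse_state(), p, "on", TRUE, 60)
  expect_equal(state_vec(s), state_vec(oracle), tolerance = 1e-8)
})

test_that("background decay over 24 h follows the exponential closed form", {
  p <- plasticity_params()
  s0 <- synapse_state(d_fast = 1, n_fast = 0, d_slow = 1, n_slow = 0)
  seg <- segment(24 * 3600, "background", kc = FALSE)
  s <- propagate_segment(s0, seg, p)
  # 2.7e-3 min^-1 * 1440 min = 3.888 e-foldings
  expect_equal(s$d_fast, 0.0204863, tolerance = 1e-5)
  oracle <- ode_oracle(s0, p, "background", FALSE, 24 * 3600)
  expect_equal(state_vec(s), state_vec(oracle), tolerance = 1e-8)
})

test_that("segment rate table maps drive conditions to rates and fixed points", {
  p <- plasticity_params()
  on_paired <- segment_rates(p, segment(60, "on", kc = TRUE))
  expect_equal(on_paired$rho, c(4.3, 0.96) / 60)
  expect_equal(on_paired$x_inf, c(1, 1))
  on_unpaired <- segment_rates(p, segment(60, "on", kc = FALSE))
  expect_equal(on_unpaired$rho, c(0.26, 0.16) / 60)
  expect_equal(on_unpaired$x_inf, c(0, 0))
  bg <- segment_rates(p, segment(60, "background", kc = FALSE))
  expect_equal(bg$rho, c(2.7e-3, 1.6e-3) / 60)
  off <- segment_rates(p, segment(60, "off", kc = TRUE))
  expect_equal(off$rho, c(0, 0))
  expect_true(all(is.na(off$x_inf)))
  expect_error(segment(60, "nonsense"), "arg")
})

test_that("zero duration is the identity and negative durations are rejected", {
  p <- plasticity_params()
  s0 <- random_state()
  expect_identical(propagate_segment(s0, segment(0, "on", kc = TRUE), p), s0)
  expect_identical(propagate_numeric(s0, segment(0, "on", kc = TRUE), p), s0)
  expect_error(segment(-1, "on"), "non-negative")
  expect_error(propagate_numeric(s0, segment(10, "on", kc = TRUE), p, dt = 0),
               "positive")
  expect_error(propagate_numeric(s0, segment(10, "on", kc = TRUE), p, dt = 20),
               "exceed")
})

test_that("DAN-off freezes the fast variables while the slow ones relax", {
  p <- plasticity_params()
  s0 <- synapse_state(d_fast = 0.5, n_fast = 0.3, d_slow = 0, n_slow = 0)
  s <- propagate_segment(s0, segment(3600, "off", kc = TRUE), p)
  expect_identical(s$d_fast, 0.5)
  expect_identical(s$n_fast, 0.3)
  # slow variables reach the (frozen) fast fixed point: tau_d = 30 s << 1 h
  expect_equal(s$d_slow, 0.5, tolerance = 1e-10)
  expect_equal(s$n_slow, 0.3 * (1 - exp(-6)), tolerance = 1e-9)
})

test_that("analytic propagation agrees with RK4 and deSolve on random segments", {
  set.seed(42)
  for (i in 1:40) {
    p <- random_params()
    s0 <- random_state()
    seg <- random_segment()
    a <- propagate_segment(s0, seg, p)
    b <- propagate_numeric(s0, seg, p, dt = 0.01)
    expect_equal(state_vec(a), state_vec(b), tolerance = 1e-6)
    o <- ode_oracle(s0, p, seg$dan, seg$kc, seg$duration_s)
    expect_equal(state_vec(a), state_vec(o), tolerance = 1e-7)
  }
})

test_that("the resonance rho*tau = 1 is handled by the analytic limit", {
  # pairing rate chosen so the fast relaxation rate equals 1/tau exactly,
  # plus nearby near-degenerate values that stress the general branch
  for (eps in c(0, 1e-12, -1e-12, 1e-6, -1e-6, 1e-3)) {
    tau <- 30
    p <- plasticity_params(a_d = (1 + eps) * 60 / tau, tau_d_s = tau)
    s0 <- synapse_state(d_fast = 0.2, n_fast = 0, d_slow = 0.7, n_slow = 0)
    seg <- segment(45, "on", kc = TRUE)
    a <- propagate_segment(s0, seg, p)
    b <- propagate_numeric(s0, seg, p, dt = 0.001)
    expect_equal(a$d_slow, b$d_slow, tolerance = 1e-8)
    o <- ode_oracle(s0, p, "on", TRUE, 45)
    expect_equal(a$d_slow, o$d_slow, tolerance = 1e-8)
  }
})

test_that("all state variables stay within [0, 1] on randomized schedules", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_params()
    segs <- replicate(8, random_segment(durations = c(1, 10, 60, 600)),
                      simplify = FALSE)
    traj <- run_schedule(segs, p)
    vals <- unlist(traj[, c("d_fast", "n_fast", "d_slow", "n_slow")])
    expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
  }
})

test_that("variables are non-decreasing during one uninterrupted pairing", {
  p <- plasticity_params()
  seg <- list(segment(300, "on", kc = c(A = TRUE, B = FALSE)))
  traj <- run_schedule(seg, p, sample_times = seq(1, 299, by = 7))
  a <- traj[traj$synapse_class == "A", ]
  a <- a[order(a$time_s), ]
  for (v in c("d_fast", "n_fast", "d_slow", "n_slow")) {
    expect_true(all(diff(a[[v]]) >= -1e-12), info = v)
  }
})

test_that("propagation obeys the semigroup property", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    s0 <- random_state()
    dan <- sample(c("on", "background", "off"), 1)
    kc <- sample(c(TRUE, FALSE), 1)
    t1 <- stats::runif(1, 1, 80)
    t2 <- stats::runif(1, 1, 80)
    whole <- propagate_segment(s0, segment(t1 + t2, dan, kc = kc), p)
    half1 <- propagate_segment(s0, segment(t1, dan, kc = kc), p)
    split <- propagate_segment(half1, segment(t2, dan, kc = kc), p)
    expect_equal(state_vec(whole), state_vec(split), tolerance = 1e-12)
  }
})

test_that("min^-1 rates and second durations combine consistently", {
  # the fast variable depends on drive only through rho * t, so scaling the
  # rate up and the duration down by the same factor is exact
  for (k in c(2, 10, 60)) {
    a <- propagate_segment(synapse_state(),
                           segment(120, "on", kc = TRUE),
                           plasticity_params(a_d = 1.3))
    b <- propagate_segment(synapse_state(),
                           segment(120 / k, "on", kc = TRUE),
                           plasticity_params(a_d = 1.3 * k))
    expect_identical(a$d_fast, b$d_fast)
  }
  # and the s^-1 conversion of the stored min^-1 rates is exactly /60
  r <- segment_rates(plasticity_params(a_d = 4.3),
                     segment(1, "on", kc = TRUE))
  expect_identical(r$rho[1], 4.3 / 60)
})

test_that("run_schedule samples boundaries and arbitrary times per class", {
  p <- plasticity_params()
  segs <- list(segment(60, "on", kc = c(A = TRUE, B = FALSE)),
               segment(600, "off", kc = c(A = FALSE, B = FALSE)))
  traj <- run_schedule(segs, p, sample_times = c(30, 300))
  expect_setequal(unique(traj$time_s), c(0, 30, 60, 300, 660))
  expect_setequal(unique(traj$synapse_class), c("A", "B"))
  a <- traj[traj$synapse_class == "A", ]
  # NO expression keeps rising after the pairing ends (tau_n = 10 min)
  expect_gt(a$n_slow[a$time_s == 660], a$n_slow[a$time_s == 60])
  # the control class is untouched
  b <- traj[traj$synapse_class == "B", ]
  expect_true(all(unlist(b[, c("d_fast", "n_fast", "d_slow", "n_slow")]) == 0))
  expect_error(run_schedule(segs, p, sample_times = c(300, 30)), "increasing")
  expect_error(run_schedule(segs, p, sample_times = 10000), "beyond")
})

test_that("empty schedules return the initial state", {
  p <- plasticity_params()
  traj <- run_schedule(list(), p, sample_times = NULL)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$d_fast, 0)
})

test_that("parameter validation rejects impossible values", {
  expect_error(plasticity_params(a_d = -1), ">= 0")
  expect_error(plasticity_params(tau_d_s = 0), "> 0")
  expect_error(synapse_state(d_fast = 1.5), "outside")
})

test_that("parameter files round-trip through JSON and YAML", {
  p <- plasticity_params(a_d = 1.23, b_n_bg = 4.5e-4)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_params(p, path)
    expect_equal(unclass(read_params(path)), unclass(p), tolerance = 1e-12)
  }
  bundled <- system.file("extdata", "fitted_params.json", package = "mbplast")
  expect_equal(read_params(bundled)$a_d, 4.3)
})
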