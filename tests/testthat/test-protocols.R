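# Protocol builders and their schedule semantics

test_that("acquisition bouts have the documented structure and arithmetic", {
  p1 <- acquisition_protocol(1, pairing_s = 10)
  expect_length(p1$segments, 3L)
  expect_equal(protocol_span(p1), 130)
  expect_equal(p1$test_times, 130)

  p3 <- acquisition_protocol(3)
  paired_s <- sum(vapply(p3$segments, function(s) {
    if (s$dan == "on" && isTRUE(s$kc[["A"]])) s$duration_s else 0
  }, numeric(1)))
  expect_equal(paired_s, 180)
  expect_error(acquisition_protocol(0), ">= 1")
})

test_that("protocol builders are pure", {
  expect_identical(acquisition_protocol(3), acquisition_protocol(3))
  expect_identical(protocol_library(), protocol_library())
})

test_that("total scheduled duration equals the sum of segment durations", {
  for (p in protocol_library()) {
    expect_equal(protocol_span(p),
                 sum(vapply(p$segments, `[[`, numeric(1), "duration_s")))
    expect_true(all(p$test_times <= protocol_span(p) + 1e-9))
  }
})

test_that("retention with zero delay reproduces the base protocol's PI", {
  params <- plasticity_params()
  ro <- readout_config(12.6, "no_only")
  base <- acquisition_protocol(1)
  ret <- retention_protocol(base, delays_s = c(0, 600))
  expect_equal(simulate_protocol(ret, params, ro)$pi[1],
               simulate_protocol(base, params, ro)$pi)
  # NO-only memory grows over the first delay interval (slow expression)
  expect_gt(simulate_protocol(ret, params, ro)$pi[2],
            simulate_protocol(ret, params, ro)$pi[1])
  expect_error(retention_protocol(base, c(600, 10)), "increasing")
})

test_that("a DAN activation without odor decays the DA trace by exp(-B_D t)", {
  params <- plasticity_params()
  pre <- acquisition_protocol(3)
  dan1 <- dan_only_protocol(pre, n_activations = 1, activation_s = 60)
  traj <- run_schedule(dan1$segments, params,
                       sample_times = dan1$test_times)
  a <- traj[traj$synapse_class == "A", ]
  d_pre <- a$d_fast[a$time_s == dan1$test_times[1]]
  d_post <- a$d_fast[a$time_s == dan1$test_times[2]]
  expect_equal(d_post / d_pre, exp(-0.26), tolerance = 1e-10)
  # zero activations: the protocol reduces to its pretraining read
  dan0 <- dan_only_protocol(pre, n_activations = 0)
  expect_equal(simulate_protocol(dan0, params, readout_config(14.8, "da_only"))$pi,
               simulate_protocol(pre, params, readout_config(14.8, "da_only"))$pi)
})

test_that("odor exposure without DAN drive has exactly no effect", {
  params <- plasticity_params()
  pre <- acquisition_protocol(3)
  odor <- odor_only_protocol(pre, n_exposures = 3)
  # same schedule with the odors removed (blank time instead of exposures)
  blank_segs <- lapply(odor$segments, function(s) {
    if (s$dan == "off") segment(s$duration_s, "off", kc = c(A = FALSE, B = FALSE))
    else s
  })
  blank <- protocol(odor$name, blank_segs, cs_plus = odor$cs_plus,
                    test_times = odor$test_times)
  for (ro in list(readout_config(14.3, "multiplicative"),
                  readout_config(14.8, "da_only"))) {
    expect_identical(simulate_protocol(odor, params, ro)$pi,
                     simulate_protocol(blank, params, ro)$pi)
  }
  # fast variables are bitwise unchanged across the exposure block
  traj <- run_schedule(odor$segments, params, sample_times = odor$test_times)
  a <- traj[traj$synapse_class == "A", ]
  expect_identical(a$d_fast[a$time_s == odor$test_times[1]],
                   a$d_fast[a$time_s == max(odor$test_times)])
  expect_identical(a$n_fast[a$time_s == odor$test_times[1]],
                   a$n_fast[a$time_s == max(odor$test_times)])
})

test_that("reversal with no reversal cycles reduces to acquisition", {
  params <- plasticity_params()
  ro <- readout_config(14.3, "multiplicative")
  rev0 <- reversal_protocol(3, 0)
  acq3 <- acquisition_protocol(3)
  expect_equal(simulate_protocol(rev0, params, ro)$pi,
               simulate_protocol(acq3, params, ro)$pi)
  # during a reversal pairing the old CS+ class decays at the unpaired rate
  rev1 <- reversal_protocol(3, 1)
  traj <- run_schedule(rev1$segments, params, sample_times = c(540, 600))
  a <- traj[traj$synapse_class == "A", ]
  expect_equal(a$d_fast[a$time_s == 600] / a$d_fast[a$time_s == 540],
               exp(-0.26), tolerance = 1e-10)
})

test_that("protocols round-trip through YAML including the bundled library", {
  p <- protocol_library()$decay_24h
  path <- tempfile(fileext = ".yaml")
  write_protocol(p, path)
  q <- read_protocol(path)
  expect_equal(q$test_times, p$test_times)
  expect_equal(length(q$segments), length(p$segments))
  expect_identical(simulate_protocol(q, plasticity_params(),
                                     readout_config(12.6, "no_only"))$pi,
                   simulate_protocol(p, plasticity_params(),
                                     readout_config(12.6, "no_only"))$pi)
  bundled <- system.file("extdata", "protocols.yaml", package = "mbplast")
  lib <- read_protocol_library(bundled)
  expect_setequal(names(lib), names(protocol_library()))
})
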