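# Grid-search fitting: loss, single stages, staged pipeline

test_that("loss is zero at the generating point and does simple arithmetic", {
  ds <- noiseless_design()
  acq <- ds[ds$protocol %in% names(acq_suite()), ]
  expect_equal(loss_mse(acq, plasticity_params(), fitted_readouts()), 0)
  # shifting every observation by 0.2 costs 0.04 per record
  shifted <- acq
  shifted$pi <- pmax(pmin(shifted$pi - 0.2, 1), -1)
  # keep only rows that did not clip
  keep <- abs((acq$pi - 0.2) - shifted$pi) < 1e-12
  expect_equal(loss_mse(shifted[keep, ], plasticity_params(), fitted_readouts()),
               0.04, tolerance = 1e-12)
  # invariant to record order
  perm <- acq[rev(seq_len(nrow(acq))), ]
  expect_equal(loss_mse(perm, plasticity_params(), fitted_readouts()),
               loss_mse(acq, plasticity_params(), fitted_readouts()))
  expect_error(loss_mse(data.frame(protocol = "nope", condition = "no_null",
                                   test_time_s = 1, pi = 0),
                        plasticity_params(), fitted_readouts()),
               "no protocol definition")
})

test_that("acquisition fits recover the generating rate and gain", {
  ds <- noiseless_design()
  acq <- ds[ds$protocol %in% names(acq_suite()), ]
  fit_no <- fit_acquisition(acq, "no_null", refine = 1)
  expect_true(all(within_grid_step(fit_no, c(a_d = 4.3, g = 14.8))))
  fit_da <- fit_acquisition(acq, "da_null", refine = 1)
  expect_true(all(within_grid_step(fit_da, c(a_n = 0.96, g = 12.6))))
  expect_error(fit_acquisition(acq[0, ], "no_null"), "empty")
})

test_that("an all-chance dataset drives the gain to the grid's lower edge", {
  ds <- noiseless_design()
  acq <- ds[ds$protocol %in% names(acq_suite()) & ds$condition == "no_null", ]
  acq$pi <- 0
  fit <- fit_acquisition(acq, "no_null", refine = 1)
  expect_equal(fit$estimates$g, 0)
  expect_equal(fit$loss, 0)
})

test_that("background-decay rates are recovered from retention records", {
  ds <- noiseless_design()
  ret <- ds[ds$protocol == "decay_24h", ]
  fit <- fit_background_decay(ret, refine = 1)
  expect_true(all(within_grid_step(fit, c(b_d_bg = 2.7e-3, b_n_bg = 1.6e-3))))
  # data generated without any background decay push both rates to the
  # lower grid edge
  p0 <- plasticity_params(b_d_bg = 0, b_n_bg = 0)
  ds0 <- generate_dataset(protocol_library()["decay_24h"], p0,
                          fitted_readouts()[c("no_null", "da_null")],
                          assay_config(noise = "none"))
  fit0 <- fit_background_decay(ds0, params = p0, refine = 0)
  expect_equal(unname(unlist(fit0$estimates)), c(1e-4, 1e-4))
})

test_that("unpaired decay rates are recovered; no activations means flat loss", {
  ds <- noiseless_design()
  unp <- ds[ds$protocol == "dan_only_5x", ]
  # full refinement: the wild-type records couple the two rates into a
  # correlated valley, so a coarse grid shifts one estimate past its step
  fit <- fit_unpaired(unp, refine = 2)
  expect_true(all(within_grid_step(fit, c(b_d = 0.26, b_n = 0.16))))
  expect_false(any(fit$flat))
  # with zero activations B is unidentifiable and flagged
  protos <- list(dan_only_0x = dan_only_protocol(acquisition_protocol(3), 0))
  ds0 <- generate_dataset(protos, plasticity_params(),
                          fitted_readouts()[c("no_null", "da_null")],
                          assay_config(noise = "none"))
  fit0 <- fit_unpaired(ds0, protocols = protos, refine = 0)
  expect_true(all(fit0$flat))
})

test_that("gain refits recover both combined-rule gains and prefer the true rule", {
  p <- plasticity_params()
  cfg <- assay_config(noise = "none")
  ds_mult <- generate_dataset(acq_suite(), p,
                              list(wild_type = readout_config(14.3, "multiplicative")),
                              cfg)
  ds_add <- generate_dataset(acq_suite(), p,
                             list(wild_type = readout_config(24.6, "additive")),
                             cfg)
  fit_mult <- refit_gain(ds_mult, "multiplicative", refine = 1)
  expect_true(within_grid_step(fit_mult, c(g = 14.3)))
  fit_add <- refit_gain(ds_add, "additive", refine = 1)
  expect_true(within_grid_step(fit_add, c(g = 24.6)))
  # fitting the wrong rule to additive-generated data costs loss
  wrong <- refit_gain(ds_add, "multiplicative", refine = 1)
  expect_gt(wrong$loss, fit_add$loss)
})

test_that("the staged pipeline assembles a full parameter set in order", {
  fits <- staged_fit(noiseless_design(), refine = 2)
  expect_named(fits, c("acquisition_no_null", "acquisition_da_null", "gain",
                       "background", "unpaired", "params", "gains"),
               ignore.order = TRUE)
  expect_equal(fits$params$a_d, 4.3, tolerance = 0.02)
  expect_equal(fits$params$b_n, 0.16, tolerance = 0.02)
  expect_equal(unname(fits$gains["wild_type"]), 14.3, tolerance = 0.05)
})

test_that("grid axes refine around the incumbent without escaping the bounds", {
  ax <- grid_axis(1e-4, 1e2, 61, "log")
  z <- mbplast:::.axis_zoom(ax, 4.3, ax)
  expect_true(z$lower > 1e-4 && z$upper < 1e2)
  expect_equal(log10(z$upper) - log10(z$lower), 0.6, tolerance = 1e-9)
  edge <- mbplast:::.axis_zoom(grid_axis(0, 50, 101, "linear"), 0,
                               grid_axis(0, 50, 101, "linear"))
  expect_equal(edge$lower, 0)
  expect_equal(edge$upper, 2.5)
  expect_error(grid_axis(5, 5), "upper > lower")
  expect_error(grid_axis(0, 1, scale = "log"), "positive")
})
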