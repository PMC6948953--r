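# Weight rules, MBON activation, softmax choice and performance index

test_that("weight rules evaluate their formulas and share the naive anchor", {
  naive <- synapse_state()
  for (rule in c("da_only", "no_only", "additive", "multiplicative")) {
    expect_equal(synaptic_weight(naive, rule), 1)
  }
  s <- synapse_state(d_slow = 0.5, n_slow = 0.2)
  expect_equal(synaptic_weight(s, "da_only"), 0.5)
  expect_equal(synaptic_weight(s, "no_only"), 1.2)
  expect_equal(synaptic_weight(s, "additive"), 0.7)
  expect_equal(synaptic_weight(s, "multiplicative"), 0.6)
  expect_equal(synaptic_weight(synapse_state(d_slow = 1, n_slow = 1),
                               "multiplicative"), 0)
  expect_error(synaptic_weight(s, "geometric"), "arg")
})

test_that("additive and multiplicative rules agree to first order near zero", {
  s <- synapse_state(d_slow = 1e-3, n_slow = 1e-3)
  expect_equal(synaptic_weight(s, "additive"),
               synaptic_weight(s, "multiplicative"), tolerance = 1e-5)
})

test_that("MBON activation averages weights over the active ensemble", {
  mf <- odor_coding(mode = "mean_field")
  expect_equal(mbon_activation(c(A = 1, B = 1), "A", mf), 0.1)
  expect_equal(mbon_activation(c(A = 0.5, B = 1), "A", mf), 0.05)
  expect_error(mbon_activation(c(A = 1), "B", mf), "odor")
  sampled <- odor_coding(n_kc = 20000, mode = "sampled", seed = 3)
  # uniform weights make the draw irrelevant: r = f * w exactly
  expect_equal(mbon_activation(rep(0.8, 20000), "A", sampled), 0.08)
  expect_error(mbon_activation(rep(1, 10), "A", sampled), "per KC")
})

test_that("softmax choice is symmetric, gain-0 flat, and overflow-safe", {
  expect_equal(choice_probability(0.3, 0.9, 0), 0.5)
  expect_equal(choice_probability(0.4, 0.4, 17), 0.5)
  expect_equal(choice_probability(0.1, 0.05, 14.3), 0.6715050,
               tolerance = 1e-6)
  # translation invariance even where naive exp() would overflow
  set.seed(5)
  for (i in 1:20) {
    ra <- stats::runif(1); rb <- stats::runif(1); g <- stats::runif(1, 0, 40)
    shift <- sample(c(0.5, 500), 1)
    expect_lt(abs(choice_probability(ra + shift, rb + shift, g) -
                    choice_probability(ra, rb, g)), 1e-12)
  }
  expect_error(choice_probability(Inf, 0, 1), "finite")
})

test_that("model PI is 2P - 1, the tanh identity, and antisymmetric", {
  expect_equal(model_pi(0.1, 0.05, 14.3), 0.3430101, tolerance = 1e-6)
  expect_equal(model_pi(0.3, 0.3, 22), 0)
  set.seed(9)
  for (i in 1:50) {
    ra <- stats::runif(1); rb <- stats::runif(1); g <- stats::runif(1, 0, 40)
    pi_val <- model_pi(ra, rb, g)
    expect_equal(pi_val, 2 * choice_probability(ra, rb, g) - 1,
                 tolerance = 1e-12)
    expect_equal(pi_val, tanh(g * (ra - rb) / 2), tolerance = 1e-12)
    expect_equal(model_pi(rb, ra, g), -pi_val, tolerance = 1e-12)
  }
})

test_that("sampled odor ensembles converge to the infinite-population limit", {
  # Independent 10% ensembles overlap in ~1% of KCs; those dual-responsive
  # synapses are depressed by CS+ pairing, which biases the CS- activation.
  # The sampled PI must agree with the analytic infinite-N limit that
  # accounts for the overlap class, and the disjoint mean-field readout
  # within an O(active_fraction) tolerance.
  p <- plasticity_params()
  g <- fitted_gains()[["multiplicative"]]
  proto <- protocol_library()$acq_3x1min
  mf <- simulate_protocol(proto, p,
                          readout_config(g, "multiplicative"))$pi
  # class weights at test time (CS+ class drives both A-only and overlap
  # synapses in acquisition; the B-only class stays naive)
  traj <- run_schedule(proto$segments, p)
  at_end <- traj[traj$time_s == protocol_span(proto), ]
  w_a <- with(at_end[at_end$synapse_class == "A", ],
              (1 - d_slow) * (1 + n_slow))
  w_b <- with(at_end[at_end$synapse_class == "B", ],
              (1 - d_slow) * (1 + n_slow))
  f <- 0.1
  limit_pi <- model_pi(f * w_a, f * ((1 - f) * w_b + f * w_a), g)
  sampled <- vapply(1:100, function(s) {
    ro <- readout_config(g, "multiplicative",
                         odor_coding(n_kc = 20000, mode = "sampled", seed = s))
    simulate_protocol(proto, p, ro)$pi
  }, numeric(1))
  mc_se <- stats::sd(sampled) / sqrt(length(sampled))
  expect_lt(abs(mean(sampled) - limit_pi), 3 * mc_se)
  expect_lt(abs(mean(sampled) - mf), 0.05)
})

test_that("readout configuration validates its fields", {
  expect_error(readout_config(-1), ">= 0")
  expect_error(odor_coding(active_fraction = 0), "between")
  ro <- fitted_readouts("additive")
  expect_equal(ro$wild_type$g, 24.6)
  expect_equal(ro$no_null$weight_rule, "da_only")
  expect_equal(ro$da_null$weight_rule, "no_only")
})
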