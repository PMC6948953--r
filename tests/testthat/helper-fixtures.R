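# Shared fixtures: everything is built in code at test time.

acq_suite <- function() {
  protocol_library()[c("acq_1x10s", "acq_1x1min", "acq_3x1min", "acq_10x1min")]
}

# noiseless dataset over the full fitting design at the fitted parameters
noiseless_design <- function() {
  protos <- protocol_library()[c("acq_1x10s", "acq_1x1min", "acq_3x1min",
                                 "acq_10x1min", "decay_24h", "dan_only_5x")]
  generate_dataset(protos, plasticity_params(), fitted_readouts(),
                   assay_config(seed = 1, noise = "none"))
}

# random but bounded parameter set for property-style tests
random_params <- function() {
  plasticity_params(a_d = stats::runif(1, 0.1, 20),
                    a_n = stats::runif(1, 0.1, 20),
                    b_d = stats::runif(1, 0.01, 2),
                    b_n = stats::runif(1, 0.01, 2),
                    b_d_bg = stats::runif(1, 1e-4, 1e-2),
                    b_n_bg = stats::runif(1, 1e-4, 1e-2),
                    tau_d_s = stats::runif(1, 5, 120),
                    tau_n_s = stats::runif(1, 60, 1200))
}

random_state <- function() {
  synapse_state(d_fast = stats::runif(1), n_fast = stats::runif(1),
                d_slow = stats::runif(1), n_slow = stats::runif(1))
}

random_segment <- function(durations = c(5, 20, 60)) {
  dan <- sample(c("on", "on", "background", "off"), 1)
  segment(sample(durations, 1), dan, kc = sample(c(TRUE, FALSE), 1))
}
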