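# Protocol simulation: deterministic PI trajectories -------------------------

# MBON activation difference r(CS+) - r(CS-) at given times, mean-field
# disjoint coding. params fields may be vectors (grid rows); returns an
# m x length(times) matrix.
.dr_at_times <- function(p, params, rule, active_fraction, times) {
  stt <- .states_at_times(p$segments, params, times,
                          class_map = list(A = "A", B = "B"))
  cs_minus <- setdiff(c("A", "B"), p$cs_plus)
  wp <- .weights(stt[[p$cs_plus]]$D, stt[[p$cs_plus]]$N, rule)
  wm <- .weights(stt[[cs_minus]]$D, stt[[cs_minus]]$N, rule)
  active_fraction * (wp - wm)
}

#' Simulate a protocol and return the PI at its test times
#'
#' Runs the plasticity model through a protocol's stimulation schedule and
#' maps the state at each test time to output-neuron activations for the two
#' odors and a deterministic performance index (the expected arena PI under
#' the softmax choice rule, reported in the CS+ frame of the protocol).
#'
#' With mean-field coding (the default) the two odors drive disjoint synapse
#' classes and the result is deterministic. With sampled coding the two
#' active KC ensembles are drawn from the coding's seed and may overlap; KCs
#' responding to both odors form a third synapse class whose plasticity is
#' driven by the union of the two odors' schedules.
#'
#' @param p an `mb_protocol`.
#' @param params a [plasticity_params()] object.
#' @param readout a [readout_config()].
#' @param times times (seconds) at which to read the PI; defaults to the
#'   protocol's `test_times`.
#' @return A data.frame with columns `time_s`, `r_cs_plus`, `r_cs_minus`,
#'   `pi`.
#' @examples
#' sim <- simulate_protocol(acquisition_protocol(3), plasticity_params(),
#'                          readout_config(14.3, "multiplicative"))
#' sim$pi
#' @export
simulate_protocol <- function(p, params, readout, times = NULL) {
  stopifnot(inherits(p, "mb_protocol"), inherits(readout, "readout_config"))
  .check_params(params)
  if (.param_len(params) != 1L) {
    stop("simulate_protocol expects scalar parameters", call. = FALSE)
  }
  times <- times %||% p$test_times
  coding <- readout$coding
  cs_minus <- setdiff(c("A", "B"), p$cs_plus)
  if (coding$mode == "mean_field") {
    stt <- .states_at_times(p$segments, params, times,
                            class_map = list(A = "A", B = "B"))
    w <- lapply(stt, function(s) .weights(s$D[1, ], s$N[1, ], readout$weight_rule))
    f <- coding$active_fraction
    r_a <- f * w$A
    r_b <- f * w$B
  } else {
    sets <- coding$active_sets
    n_ab <- length(intersect(sets$A, sets$B))
    n_a_only <- length(sets$A) - n_ab
    n_b_only <- length(sets$B) - n_ab
    stt <- .states_at_times(p$segments, params, times,
                            class_map = list(A = "A", B = "B",
                                             AB = c("A", "B")))
    w <- lapply(stt, function(s) .weights(s$D[1, ], s$N[1, ], readout$weight_rule))
    r_a <- (n_a_only * w$A + n_ab * w$AB) / coding$n_kc
    r_b <- (n_b_only * w$B + n_ab * w$AB) / coding$n_kc
  }
  rp <- if (p$cs_plus == "A") r_a else r_b
  rm <- if (p$cs_plus == "A") r_b else r_a
  data.frame(time_s = times, r_cs_plus = rp, r_cs_minus = rm,
             pi = model_pi(rp, rm, readout$g))
}
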