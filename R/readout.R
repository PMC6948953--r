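# From plasticity state to synaptic weight, MBON activation, choice
# probability and performance index -----------------------------------------

.weight_rules <- c("da_only", "no_only", "additive", "multiplicative")

# vectorized weight rules; the additive rule is anchored so the naive weight
# (D = N = 0) is 1 under every rule
.weights <- function(D, N, rule) {
  switch(rule,
         da_only = 1 - D,
         no_only = 1 + N,
         additive = 1 + N - D,
         multiplicative = (1 - D) * (1 + N),
         stop("unknown weight rule: ", rule, call. = FALSE))
}

#' Normalized KC-to-MBON synaptic weight
#'
#' Combines the slow expressed plasticity effects `D` (dopamine-mediated
#' depression) and `N` (nitric-oxide-mediated facilitation) into a
#' normalized synaptic weight. Four rules are supported: `da_only`
#' (`w = 1 - D`), `no_only` (`w = 1 + N`), `additive` (`w = 1 + N - D`) and
#' `multiplicative` (`w = (1 - D)(1 + N)`). The additive rule is anchored so
#' that the naive state has `w = 1`, like the other rules.
#'
#' @param state a [synapse_state()] (only the slow fields enter).
#' @param rule one of `"da_only"`, `"no_only"`, `"additive"`,
#'   `"multiplicative"`.
#' @return Numeric weight(s), `>= 0` for states within bounds.
#' @export
synaptic_weight <- function(state, rule = .weight_rules) {
  rule <- match.arg(rule)
  stopifnot(inherits(state, "synapse_state"))
  .weights(state$d_slow, state$n_slow, rule)
}

#' Odor coding scheme across the Kenyon-cell population
#'
#' Each odor activates a sparse fraction of the KC population. In
#' `mean_field` mode (the default, and the deterministic scheme used for
#' fitting) the two odors drive disjoint synapse classes and the population
#' is taken to its large-size limit. In `sampled` mode each odor's active
#' ensemble is drawn uniformly and independently, so ensembles may overlap
#' (an expected `active_fraction^2` of KCs respond to both odors and are
#' tracked as a third synapse class).
#'
#' @param n_kc total number of KCs (sampled mode).
#' @param active_fraction fraction of KCs activated per odor, in (0, 1).
#' @param mode `"mean_field"` or `"sampled"`.
#' @param seed integer seed used to draw the active sets in sampled mode.
#' @return An object of class `odor_coding`. In sampled mode it carries
#'   `active_sets`, a named list of KC index vectors for odors A and B.
#' @export
odor_coding <- function(n_kc = 2000, active_fraction = 0.10,
                        mode = c("mean_field", "sampled"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(active_fraction) || active_fraction <= 0 ||
      active_fraction >= 1) {
    stop("active_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(n_kc) || n_kc < 2) stop("n_kc must be >= 2", call. = FALSE)
  sets <- NULL
  if (mode == "sampled") {
    k <- round(active_fraction * n_kc)
    sets <- .with_seed(seed, list(A = sort(sample.int(n_kc, k)),
                                  B = sort(sample.int(n_kc, k))))
  }
  structure(list(n_kc = n_kc, active_fraction = active_fraction, mode = mode,
                 seed = seed, active_sets = sets),
            class = "odor_coding")
}

#' MBON activation evoked by an odor
#'
#' The output-neuron activation is the average synaptic weight over the whole
#' KC population, counting only KCs active for the presented odor:
#' `r = (1/N_KC) * sum_i w_i * s_i`. In mean-field mode this reduces to
#' `active_fraction * w_class(odor)`; in sampled mode the sum runs over the
#' drawn active set.
#'
#' @param weights in mean-field mode, a named numeric vector of per-class
#'   weights (names = odors); in sampled mode, a numeric vector of per-KC
#'   weights of length `coding$n_kc`.
#' @param odor odor label (`"A"` or `"B"`).
#' @param coding an [odor_coding()] object.
#' @return The scalar activation `r`.
#' @export
mbon_activation <- function(weights, odor, coding = odor_coding()) {
  stopifnot(inherits(coding, "odor_coding"))
  if (coding$mode == "mean_field") {
    if (is.null(names(weights)) || !odor %in% names(weights)) {
      stop("no weight class for odor '", odor, "'", call. = FALSE)
    }
    return(coding$active_fraction * unname(weights[odor]))
  }
  set <- coding$active_sets[[odor]]
  if (is.null(set)) stop("no active KC set for odor '", odor, "'", call. = FALSE)
  if (length(weights) != coding$n_kc) {
    stop("need one weight per KC (", coding$n_kc, ")", call. = FALSE)
  }
  sum(weights[set]) / coding$n_kc
}

#' Softmax choice probability between two odors
#'
#' Probability that a fly chooses odor A given the MBON activations evoked by
#' the two odors: `P(A) = exp(g r_a) / (exp(g r_a) + exp(g r_b))`. The
#' implementation works on the activation difference (equivalent to shifting
#' both exponents by their maximum), so arbitrarily large common activations
#' can neither overflow nor lose precision. `g = 0` gives chance behavior
#' (P = 1/2) regardless of the activations.
#'
#' @param r_a,r_b MBON activations for odors A and B (finite).
#' @param g softmax gain, `>= 0`.
#' @return `P(A)`, strictly inside (0, 1) for finite inputs.
#' @export
choice_probability <- function(r_a, r_b, g) {
  if (any(!is.finite(r_a)) || any(!is.finite(r_b)) || any(!is.finite(g))) {
    stop("activations and gain must be finite", call. = FALSE)
  }
  1 / (1 + exp(g * (r_b - r_a)))
}

#' Deterministic model performance index
#'
#' The arena performance index is the expected value of
#' (flies at odor A - flies at odor B) / total flies under the softmax
#' choice model: `PI = 2 P(A) - 1 = tanh(g (r_a - r_b) / 2)`. The sign
#' convention puts odor A in the trained (CS+) slot, and the modeled MBON
#' drives approach, so dopaminergic depression of CS+ synapses gives a
#' negative PI while NO-mediated facilitation gives a positive one.
#'
#' @inheritParams choice_probability
#' @return PI in (-1, 1).
#' @export
model_pi <- function(r_a, r_b, g) {
  if (any(!is.finite(r_a)) || any(!is.finite(r_b)) || any(!is.finite(g))) {
    stop("activations and gain must be finite", call. = FALSE)
  }
  tanh(g * (r_a - r_b) / 2)
}

#' Behavioral readout configuration
#'
#' Bundles the softmax gain, the weight-combination rule and the KC odor
#' coding scheme into one object consumed by [simulate_protocol()] and the
#' fitting routines.
#'
#' @param g softmax gain (dimensionless, `>= 0`).
#' @param weight_rule one of the rules of [synaptic_weight()].
#' @param coding an [odor_coding()] object.
#' @return An object of class `readout_config`.
#' @export
readout_config <- function(g, weight_rule = .weight_rules,
                           coding = odor_coding()) {
  weight_rule <- match.arg(weight_rule)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0) {
    stop("g must be a single finite number >= 0", call. = FALSE)
  }
  stopifnot(inherits(coding, "odor_coding"))
  structure(list(g = g, weight_rule = weight_rule, coding = coding),
            class = "readout_config")
}

#' @export
print.readout_config <- function(x, ...) {
  cat(sprintf("readout: g = %g, rule = %s, coding = %s (f = %g)\n",
              x$g, x$weight_rule, x$coding$mode, x$coding$active_fraction))
  invisible(x)
}

#' Readout configurations matching the fitted model
#'
#' Convenience bundle of per-condition readouts: the NO-null condition reads
#' out through the DA-only rule, the DA-null condition through the NO-only
#' rule, and the wild type through the chosen combination rule, each with its
#' fitted gain (see [fitted_gains()]).
#'
#' @param wild_rule combination rule for the wild-type condition.
#' @return Named list of [readout_config()]s with elements `no_null`,
#'   `da_null`, `wild_type`.
#' @export
fitted_readouts <- function(wild_rule = c("multiplicative", "additive")) {
  wild_rule <- match.arg(wild_rule)
  gg <- fitted_gains()
  list(no_null = readout_config(gg[["no_null"]], "da_only"),
       da_null = readout_config(gg[["da_null"]], "no_only"),
       wild_type = readout_config(gg[[wild_rule]], wild_rule))
}

# weight rule implied by a genotype condition
.rule_for_condition <- function(condition, wild_rule) {
  switch(condition,
         no_null = "da_only",
         da_null = "no_only",
         wild_type = wild_rule,
         stop("unknown condition: ", condition, call. = FALSE))
}
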