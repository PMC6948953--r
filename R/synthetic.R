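# Synthetic arena-assay behavioral datasets ----------------------------------
#
# The arena assay scores a group of ~20 flies choosing between two odor
# quadrant pairs; PI = (flies at A - flies at B) / total. The generator
# models each fly as an independent Bernoulli chooser with the model's
# softmax probability, samples reciprocal group pairs (odor identities
# swapped between groups, which cancels any fixed odor-identity bias), and
# emits records in the schema the fitting routines consume.

#' Arena assay configuration
#'
#' @param n_flies flies per group (the assay statistic is a count over
#'   these).
#' @param n_replicates reciprocal assay pairs per condition cell; typical
#'   experiments run 8-16.
#' @param reciprocal whether each replicate is a reciprocal pair of groups
#'   with odor identities swapped (recommended; on by default).
#' @param seed integer seed for the generator.
#' @param noise `"binomial"` for fly-count sampling noise, `"none"` to emit
#'   the deterministic model PI exactly.
#' @param odor_bias fixed additive preference (on the PI scale) for odor A
#'   irrespective of training, used to demonstrate that reciprocal averaging
#'   cancels such biases. Default 0.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(n_flies = 20, n_replicates = 12, reciprocal = TRUE,
                         seed = NULL, noise = c("binomial", "none"),
                         odor_bias = 0) {
  noise <- match.arg(noise)
  if (!is.numeric(n_flies) || n_flies < 1) stop("n_flies must be >= 1", call. = FALSE)
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  if (abs(odor_bias) > 1) stop("odor_bias must lie in [-1, 1]", call. = FALSE)
  structure(list(n_flies = as.integer(n_flies),
                 n_replicates = as.integer(n_replicates),
                 reciprocal = isTRUE(reciprocal), seed = seed, noise = noise,
                 odor_bias = odor_bias),
            class = "assay_config")
}

#' Sample one arena assay
#'
#' Draws the number of flies in the odor-A quadrants binomially with the
#' given choice probability and returns the empirical performance index
#' `(count_A - count_B) / n_flies`.
#'
#' @param p_a probability that a fly chooses odor A, in `[0, 1]`.
#' @param config an [assay_config()].
#' @param seed optional seed for this single draw.
#' @return An object of class `synthetic_assay` with fields `count_a`,
#'   `count_b`, `pi`, `p_a`, `n_flies`.
#' @export
sample_assay <- function(p_a, config = assay_config(), seed = NULL) {
  if (!is.numeric(p_a) || length(p_a) != 1L || is.na(p_a) || p_a < 0 || p_a > 1) {
    stop("p_a must be a probability in [0, 1]", call. = FALSE)
  }
  n <- config$n_flies
  count_a <- .with_seed(seed, stats::rbinom(1L, n, p_a))
  structure(list(count_a = count_a, count_b = n - count_a,
                 pi = (2 * count_a - n) / n, p_a = p_a, n_flies = n),
            class = "synthetic_assay")
}

#' Average a reciprocal pair of assays
#'
#' In a reciprocal design the second group is trained with the odor
#' identities swapped, so its measured PI (in the fixed odor frame) carries
#' the learned preference with opposite sign but any odor-identity bias with
#' the same sign. The reciprocal mean `(PI_1 - PI_2) / 2` re-expresses both
#' groups in the CS+ frame and cancels the bias exactly in expectation.
#'
#' @param assay_1 assay of the group trained with odor A as CS+.
#' @param assay_2 assay of the group trained with odor B as CS+ (PI still
#'   measured in the odor-A frame).
#' @return The reciprocal-averaged PI (single number).
#' @export
reciprocal_average <- function(assay_1, assay_2) {
  stopifnot(inherits(assay_1, "synthetic_assay"),
            inherits(assay_2, "synthetic_assay"))
  p1 <- attr(assay_1, "protocol")
  p2 <- attr(assay_2, "protocol")
  if (!is.null(p1) && !is.null(p2) && !identical(p1, p2)) {
    stop("reciprocal assays must come from the same protocol", call. = FALSE)
  }
  (assay_1$pi - assay_2$pi) / 2
}

.clamp01 <- function(p) pmin(pmax(p, 0), 1)

#' Generate a synthetic behavioral dataset
#'
#' For every combination of protocol, condition and test time, simulates the
#' deterministic model PI, converts it to a choice probability
#' `p = (PI + 1) / 2`, and (unless `noise = "none"`) samples
#' `n_replicates` reciprocal assay pairs of `n_flies` Bernoulli choosers.
#' Each replicate pair is emitted as one record; with `noise = "none"` a
#' single record per cell carries the deterministic PI bitwise.
#'
#' @param protocols named list of `mb_protocol`s to include.
#' @param params a [plasticity_params()] object (the generating truth).
#' @param readouts named list of per-condition [readout_config()]s (see
#'   [fitted_readouts()]); the conditions generated are `names(readouts)`.
#' @param config an [assay_config()].
#' @return A data.frame of class `c("behavior_dataset", "data.frame")` with
#'   columns `protocol`, `condition`, `test_time_s`, `pi`, `replicate`,
#'   `n_replicates`, `n_flies`, `source`, and a `meta` attribute recording
#'   the generating parameters and seed.
#' @export
generate_dataset <- function(protocols, params, readouts = fitted_readouts(),
                             config = assay_config()) {
  if (!length(protocols)) stop("protocol suite is empty", call. = FALSE)
  if (is.null(names(protocols)) || any(names(protocols) == "")) {
    names(protocols) <- vapply(protocols, `[[`, character(1), "name")
  }
  .check_params(params)
  .with_seed(config$seed, {
    recs <- list()
    for (pname in names(protocols)) {
      p <- protocols[[pname]]
      for (cond in names(readouts)) {
        sim <- simulate_protocol(p, params, readouts[[cond]])
        for (i in seq_len(nrow(sim))) {
          pi_det <- sim$pi[i]
          if (config$noise == "none") {
            recs[[length(recs) + 1L]] <- data.frame(
              protocol = pname, condition = cond,
              test_time_s = sim$time_s[i], pi = pi_det, replicate = 1L,
              n_replicates = 1L, n_flies = config$n_flies,
              source = "synthetic")
            next
          }
          sgn <- if (p$cs_plus == "A") 1 else -1
          p1 <- .clamp01((sgn * pi_det + config$odor_bias + 1) / 2)
          p2 <- .clamp01((-sgn * pi_det + config$odor_bias + 1) / 2)
          for (r in seq_len(config$n_replicates)) {
            a1 <- sample_assay(p1, config)
            pi_obs <- if (config$reciprocal) {
              a2 <- sample_assay(p2, config)
              sgn * reciprocal_average(a1, a2)
            } else {
              sgn * a1$pi
            }
            recs[[length(recs) + 1L]] <- data.frame(
              protocol = pname, condition = cond,
              test_time_s = sim$time_s[i], pi = pi_obs, replicate = r,
              n_replicates = config$n_replicates, n_flies = config$n_flies,
              source = "synthetic")
          }
        }
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "meta") <- list(
      generator = "mbplast::generate_dataset",
      seed = config$seed, noise = config$noise,
      n_flies = config$n_flies, n_replicates = config$n_replicates,
      reciprocal = config$reciprocal, odor_bias = config$odor_bias,
      params = unclass(params),
      gains = lapply(readouts, `[[`, "g"),
      rules = lapply(readouts, `[[`, "weight_rule"))
    class(out) <- c("behavior_dataset", "data.frame")
    out
  })
}

#' Read or write a behavior dataset as CSV
#'
#' `write_behavior_dataset()` writes the records as plain CSV plus a sidecar
#' JSON manifest (`<path>.json`) carrying the generating parameters when the
#' dataset has them. `read_behavior_dataset()` restores both.
#'
#' @param dataset a behavior dataset data.frame.
#' @param path CSV file path.
#' @return `read_behavior_dataset()` returns the dataset;
#'   `write_behavior_dataset()` returns `path` invisibly.
#' @export
write_behavior_dataset <- function(dataset, path) {
  .check_dataset(dataset)
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  meta <- attr(dataset, "meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_behavior_dataset
#' @export
read_behavior_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_dataset(out)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  class(out) <- c("behavior_dataset", "data.frame")
  out
}
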