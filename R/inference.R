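# Staged grid-search inference -----------------------------------------------
#
# The fitting pipeline mirrors the staged design of the study: (1) pairing
# rates and gains from single-pathway acquisition data, (2) background decay
# rates from retention data, (3) unpaired decay rates from DAN-activation
# data, (4) an optional gain refit for the combined-pathway rules; reversal
# dynamics are then predicted with nothing refit. Every stage is an
# exhaustive scan over a (optionally refined) grid minimizing the mean
# squared difference between model and observed PI, with ties broken by the
# first point in scan order.

#' Grid axis for one free parameter
#'
#' @param lower,upper axis bounds (`lower > 0` required on the log scale).
#' @param n number of grid points, `>= 2`.
#' @param scale `"log"` (points equispaced in log10) or `"linear"`.
#' @return An object of class `grid_axis`.
#' @export
grid_axis <- function(lower, upper, n = 61, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!is.numeric(lower) || !is.numeric(upper) || upper <= lower) {
    stop("need numeric bounds with upper > lower", call. = FALSE)
  }
  if (scale == "log" && lower <= 0) {
    stop("log-scale axis needs positive bounds", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 grid points per axis", call. = FALSE)
  structure(list(lower = lower, upper = upper, n = as.integer(n),
                 scale = scale),
            class = "grid_axis")
}

.axis_values <- function(a) {
  if (a$scale == "log") 10^seq(log10(a$lower), log10(a$upper), length.out = a$n)
  else seq(a$lower, a$upper, length.out = a$n)
}

# grid spacing: decades per interval (log) or absolute step (linear)
.axis_step <- function(a) {
  if (a$scale == "log") (log10(a$upper) - log10(a$lower)) / (a$n - 1)
  else (a$upper - a$lower) / (a$n - 1)
}

# shrink the axis span tenfold around `center`, clipped to `bounds` (the
# original search box) so refinement can never escape it
.axis_zoom <- function(a, center, bounds) {
  if (a$scale == "log") {
    half <- (log10(a$upper) - log10(a$lower)) / 20
    lo <- max(10^(log10(center) - half), bounds$lower)
    hi <- min(10^(log10(center) + half), bounds$upper)
  } else {
    half <- (a$upper - a$lower) / 20
    lo <- max(center - half, bounds$lower)
    hi <- min(center + half, bounds$upper)
  }
  if (hi <= lo) stop("degenerate refinement axis", call. = FALSE)
  grid_axis(lo, hi, a$n, a$scale)
}

#' Default search grids
#'
#' Rates are searched on a log grid spanning 1e-4 to 1e2 min^-1 with 61
#' points; the gain on a linear grid over 0..50 with 101 points. Two
#' refinement stages each shrink the span tenfold around the incumbent, for
#' a final resolution of about 0.23% on rates and 0.005 on the gain -- much
#' finer than the precision to which the fitted values are quoted.
#'
#' @name default_grids
#' @return A `grid_axis`.
#' @export
default_rate_axis <- function() grid_axis(1e-4, 1e2, 61, "log")

#' @rdname default_grids
#' @export
default_gain_axis <- function() grid_axis(0, 50, 101, "linear")

.fit_result <- function(estimates, loss, fixed, axes, flat, n_obs,
                        surface = NULL) {
  steps <- vapply(axes, .axis_step, numeric(1))
  scales <- vapply(axes, `[[`, character(1), "scale")
  structure(list(estimates = estimates, loss = loss, fixed = fixed,
                 grid = axes, grid_step = steps, grid_scale = scales,
                 flat = flat, n_obs = n_obs, surface = surface),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("grid-search fit (", x$n_obs, " observations)\n", sep = "")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-8s = %-12.6g (final grid step %.3g on %s scale)%s\n",
                nm, x$estimates[[nm]], x$grid_step[[nm]], x$grid_scale[[nm]],
                if (isTRUE(x$flat[[nm]])) "  [unidentifiable: flat loss]" else ""))
  }
  cat(sprintf("  mse      = %.6g\n", x$loss))
  invisible(x)
}

#' Is a recovered estimate within one final grid step of a reference value?
#'
#' @param fit a `fit_result`.
#' @param truth named numeric vector of reference values.
#' @return Named logical vector over the parameters in `truth`.
#' @export
within_grid_step <- function(fit, truth) {
  stopifnot(inherits(fit, "fit_result"))
  out <- logical(length(truth))
  names(out) <- names(truth)
  for (nm in names(truth)) {
    est <- fit$estimates[[nm]]
    step <- fit$grid_step[[nm]]
    out[nm] <- if (fit$grid_scale[[nm]] == "log") {
      abs(log10(est) - log10(truth[[nm]])) <= step + 1e-12
    } else {
      abs(est - truth[[nm]]) <= step + 1e-12
    }
  }
  out
}

.check_dataset <- function(dataset) {
  need <- c("protocol", "condition", "test_time_s", "pi")
  missing <- setdiff(need, names(dataset))
  if (length(missing)) {
    stop("dataset is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(dataset)) stop("dataset is empty", call. = FALSE)
  if (any(abs(dataset$pi) > 1 + 1e-9)) {
    stop("PI values must lie in [-1, 1]", call. = FALSE)
  }
  invisible(dataset)
}

.resolve_protocols <- function(names_used, protocols) {
  missing <- setdiff(unique(names_used), names(protocols))
  if (length(missing)) {
    stop("no protocol definition for: ", paste(missing, collapse = ", "),
         "; available: ", paste(names(protocols), collapse = ", "),
         call. = FALSE)
  }
  protocols[unique(names_used)]
}

# r(CS+) - r(CS-) for every dataset row; params fields may be grid vectors.
# Returns an m x nrow(rows) matrix.
.dr_matrix <- function(rows, protos, params, rule, f) {
  m <- .param_len(params)
  out <- matrix(NA_real_, m, nrow(rows))
  for (nm in unique(rows$protocol)) {
    sel <- rows$protocol == nm
    tt <- sort(unique(rows$test_time_s[sel]))
    dr <- .dr_at_times(protos[[nm]], params, rule, f, tt)
    out[, which(sel)] <- dr[, match(rows$test_time_s[sel], tt), drop = FALSE]
  }
  out
}

#' Mean squared error between model and observed PIs
#'
#' Simulates every record's protocol at its test time under the weight rule
#' implied by its genotype condition (`no_null` reads out DA-only, `da_null`
#' NO-only, `wild_type` the readout's own combination rule) and returns the
#' mean over records of the squared PI difference. Deterministic under
#' mean-field coding; invariant to record order.
#'
#' @param dataset a behavior dataset (see [generate_dataset()]).
#' @param params a [plasticity_params()] object (scalars).
#' @param readout a single [readout_config()] applied to every condition, or
#'   a named list of per-condition readouts.
#' @param protocols named list resolving the dataset's protocol labels.
#' @return The mean squared error (single number).
#' @export
loss_mse <- function(dataset, params, readout,
                     protocols = protocol_library()) {
  .check_dataset(dataset)
  .check_params(params)
  protos <- .resolve_protocols(dataset$protocol, protocols)
  sse <- 0
  for (cond in unique(dataset$condition)) {
    rows <- dataset[dataset$condition == cond, , drop = FALSE]
    ro <- if (inherits(readout, "readout_config")) readout else readout[[cond]]
    if (is.null(ro)) stop("no readout for condition ", cond, call. = FALSE)
    rule <- .rule_for_condition(cond, ro$weight_rule)
    dr <- .dr_matrix(rows, protos, params, rule, ro$coding$active_fraction)
    sse <- sse + sum((tanh(ro$g * dr[1, ] / 2) - rows$pi)^2)
  }
  sse / nrow(dataset)
}

# first index of the minimum when scanning a rate x gain loss matrix with the
# rate as the outer loop -- the documented tie-break order
.scan_min_rg <- function(L) {
  v <- as.vector(t(L))
  idx <- which.min(v)
  ng <- ncol(L)
  list(ri = (idx - 1L) %/% ng + 1L, gi = (idx - 1L) %% ng + 1L,
       loss = v[idx])
}

#' Fit a pairing rate and gain to single-pathway acquisition data
#'
#' Grid search over the pairing rate of the active pathway and the softmax
#' gain, minimizing the mean squared PI error on acquisition protocols for
#' one single-pathway condition: `no_null` frees `a_d` under the DA-only
#' rule, `da_null` frees `a_n` under the NO-only rule. The scan is
#' exhaustive at each stage; `refine` further stages shrink the grid
#' tenfold around the incumbent. Ties go to the first point in scan order
#' (rate outer, gain inner, both ascending).
#'
#' @param dataset behavior dataset containing acquisition records for the
#'   chosen condition.
#' @param condition `"no_null"` or `"da_null"`.
#' @param grid optional list with `grid_axis` elements `rate` and `g`.
#' @param params base parameters for everything not being fitted.
#' @param protocols named protocol list resolving the dataset labels.
#' @param active_fraction KC fraction per odor of the mean-field readout.
#' @param refine number of refinement stages (`>= 0`).
#' @return A `fit_result`; `estimates` holds the freed rate (`a_d` or `a_n`)
#'   and `g`.
#' @export
fit_acquisition <- function(dataset, condition = c("no_null", "da_null"),
                            grid = NULL, params = plasticity_params(),
                            protocols = protocol_library(),
                            active_fraction = 0.10, refine = 2) {
  condition <- match.arg(condition)
  .check_dataset(dataset)
  rows <- dataset[dataset$condition == condition, , drop = FALSE]
  if (!nrow(rows)) stop("no records for condition ", condition, call. = FALSE)
  rate_name <- if (condition == "no_null") "a_d" else "a_n"
  rule <- if (condition == "no_null") "da_only" else "no_only"
  protos <- .resolve_protocols(rows$protocol, protocols)
  axes <- list(rate = grid$rate %||% default_rate_axis(),
               g = grid$g %||% default_gain_axis())
  bounds <- axes
  best <- NULL
  surface <- NULL
  for (stage in 0:refine) {
    rate_vals <- .axis_values(axes$rate)
    g_vals <- .axis_values(axes$g)
    pg <- unclass(params)
    pg[[rate_name]] <- rate_vals
    DR <- .dr_matrix(rows, protos, pg, rule, active_fraction)
    Y <- matrix(rows$pi, nrow(DR), ncol(DR), byrow = TRUE)
    L <- vapply(g_vals,
                function(g) rowMeans((tanh(g * DR / 2) - Y)^2),
                numeric(length(rate_vals)))
    hit <- .scan_min_rg(L)
    best <- list(rate = rate_vals[hit$ri], g = g_vals[hit$gi], loss = hit$loss,
                 ri = hit$ri, gi = hit$gi, L = L)
    if (stage < refine) {
      axes$rate <- .axis_zoom(axes$rate, best$rate, bounds$rate)
      axes$g <- .axis_zoom(axes$g, best$g, bounds$g)
    }
  }
  surface <- data.frame(
    rate = rep(.axis_values(axes$rate), times = length(.axis_values(axes$g))),
    g = rep(.axis_values(axes$g), each = axes$rate$n),
    loss = as.vector(best$L))
  names(surface)[1] <- rate_name
  flat <- c(diff(range(best$L[, best$gi])) < 1e-14,
            diff(range(best$L[best$ri, ])) < 1e-14)
  names(flat) <- c(rate_name, "g")
  est <- stats::setNames(c(best$rate, best$g), c(rate_name, "g"))
  fixed <- unclass(params)[setdiff(.param_fields, rate_name)]
  fixed$weight_rule <- rule
  fixed$condition <- condition
  .fit_result(as.list(est), best$loss, fixed,
              stats::setNames(axes, c(rate_name, "g")), flat, nrow(rows),
              surface)
}

# shared machinery for the two rate-pair fits (background decay, unpaired
# decay): frees two rates jointly on a 2-D grid with everything else fixed;
# gains and rules are per condition
.fit_rate_pair <- function(dataset, free, params, gains, wild_rule, grid,
                           protocols, active_fraction, refine) {
  .check_dataset(dataset)
  protos <- .resolve_protocols(dataset$protocol, protocols)
  conds <- unique(dataset$condition)
  # wild-type records read out through the combination rule; if no explicit
  # wild_type gain is given, use the gain fitted for that rule
  gain_of <- function(cond) {
    if (cond %in% names(gains)) return(gains[[cond]])
    if (cond == "wild_type" && wild_rule %in% names(gains)) {
      return(gains[[wild_rule]])
    }
    stop("no gain supplied for condition ", cond, call. = FALSE)
  }
  for (cond in conds) gain_of(cond)
  axes <- list(grid[[free[1]]] %||% default_rate_axis(),
               grid[[free[2]]] %||% default_rate_axis())
  names(axes) <- free
  bounds <- axes
  best <- NULL
  for (stage in 0:refine) {
    v1 <- .axis_values(axes[[1]])
    v2 <- .axis_values(axes[[2]])
    n1 <- length(v1)
    n2 <- length(v2)
    pg <- unclass(params)
    pg[[free[1]]] <- rep(v1, each = n2)   # outer loop in scan order
    pg[[free[2]]] <- rep(v2, times = n1)
    sse <- numeric(n1 * n2)
    for (cond in conds) {
      rows <- dataset[dataset$condition == cond, , drop = FALSE]
      rule <- .rule_for_condition(cond, wild_rule)
      dr <- .dr_matrix(rows, protos, pg, rule, active_fraction)
      Y <- matrix(rows$pi, nrow(dr), ncol(dr), byrow = TRUE)
      sse <- sse + rowSums((tanh(gain_of(cond) * dr / 2) - Y)^2)
    }
    loss <- sse / nrow(dataset)
    idx <- which.min(loss)
    i1 <- (idx - 1L) %/% n2 + 1L
    i2 <- (idx - 1L) %% n2 + 1L
    best <- list(v1 = v1[i1], v2 = v2[i2], loss = loss[idx],
                 i1 = i1, i2 = i2, all = loss, n1 = n1, n2 = n2)
    if (stage < refine) {
      axes[[1]] <- .axis_zoom(axes[[1]], best$v1, bounds[[1]])
      axes[[2]] <- .axis_zoom(axes[[2]], best$v2, bounds[[2]])
    }
  }
  Lm <- matrix(best$all, best$n2, best$n1)  # rows = axis 2, cols = axis 1
  flat <- c(diff(range(Lm[best$i2, ])) < 1e-14,
            diff(range(Lm[, best$i1])) < 1e-14)
  names(flat) <- free
  surface <- data.frame(rep(v1, each = best$n2), rep(v2, times = best$n1),
                        best$all)
  names(surface) <- c(free, "loss")
  est <- stats::setNames(list(best$v1, best$v2), free)
  fixed <- unclass(params)[setdiff(.param_fields, free)]
  fixed$gains <- gains
  .fit_result(est, best$loss, fixed, axes, flat, nrow(dataset), surface)
}

#' Fit the background-decay rates to retention data
#'
#' Frees the background decay rates `b_d_bg` and `b_n_bg` jointly on a 2-D
#' grid, holding every other parameter (and the per-condition gains) at
#' their previously fitted values, and minimizing the mean squared PI error
#' on retention records (PI read at delays after training, with spontaneous
#' background DAN activity eroding the traces in between).
#'
#' @inheritParams fit_acquisition
#' @param gains named numeric vector of softmax gains per condition present
#'   in the dataset (e.g. `c(no_null = 14.8, da_null = 12.6)`); `wild_type`
#'   records fall back to the gain named after `wild_rule`.
#' @param wild_rule combination rule for any `wild_type` records.
#' @param grid optional list with `grid_axis` elements named after the freed
#'   rates.
#' @return A `fit_result` with estimates `b_d_bg`, `b_n_bg`.
#' @export
fit_background_decay <- function(dataset, params = plasticity_params(),
                                 gains = fitted_gains(),
                                 wild_rule = "multiplicative", grid = NULL,
                                 protocols = protocol_library(),
                                 active_fraction = 0.10, refine = 2) {
  .fit_rate_pair(dataset, c("b_d_bg", "b_n_bg"), params, gains, wild_rule,
                 grid, protocols, active_fraction, refine)
}

#' Fit the unpaired decay rates to DAN-activation data
#'
#' Frees the unpaired decay rates `b_d` and `b_n` (the rates at which an
#' active DAN erodes the traces of silent KCs) on a 2-D grid, with all other
#' parameters fixed, against records from DAN-activation-without-odor
#' designs. If a dataset contains no activations the loss is flat in these
#' rates and the result is flagged unidentifiable.
#'
#' @inheritParams fit_background_decay
#' @return A `fit_result` with estimates `b_d`, `b_n`.
#' @export
fit_unpaired <- function(dataset, params = plasticity_params(),
                         gains = fitted_gains(),
                         wild_rule = "multiplicative", grid = NULL,
                         protocols = protocol_library(),
                         active_fraction = 0.10, refine = 2) {
  .fit_rate_pair(dataset, c("b_d", "b_n"), params, gains, wild_rule,
                 grid, protocols, active_fraction, refine)
}

#' Refit the softmax gain under a combined weight rule
#'
#' With both pathway rates fixed from the single-pathway fits, frees only
#' the gain `g` under the additive or multiplicative combination rule
#' against wild-type-condition records.
#'
#' @inheritParams fit_acquisition
#' @param rule `"multiplicative"` or `"additive"`.
#' @param grid optional list with a `grid_axis` element `g`.
#' @return A `fit_result` with estimate `g`.
#' @export
refit_gain <- function(dataset, rule = c("multiplicative", "additive"),
                       params = plasticity_params(), grid = NULL,
                       protocols = protocol_library(),
                       active_fraction = 0.10, refine = 2) {
  rule <- match.arg(rule)
  .check_dataset(dataset)
  rows <- dataset[dataset$condition == "wild_type", , drop = FALSE]
  if (!nrow(rows)) stop("no wild_type records in dataset", call. = FALSE)
  protos <- .resolve_protocols(rows$protocol, protocols)
  drv <- .dr_matrix(rows, protos, unclass(params), rule, active_fraction)[1, ]
  axis <- grid$g %||% default_gain_axis()
  bound <- axis
  best <- NULL
  for (stage in 0:refine) {
    g_vals <- .axis_values(axis)
    loss <- vapply(g_vals,
                   function(g) mean((tanh(g * drv / 2) - rows$pi)^2),
                   numeric(1))
    gi <- which.min(loss)
    best <- list(g = g_vals[gi], loss = loss[gi], all = loss)
    if (stage < refine) axis <- .axis_zoom(axis, best$g, bound)
  }
  flat <- c(g = diff(range(best$all)) < 1e-14)
  fixed <- unclass(params)
  fixed$weight_rule <- rule
  .fit_result(list(g = best$g), best$loss, fixed, list(g = axis), flat,
              nrow(rows),
              surface = data.frame(g = .axis_values(axis), loss = best$all))
}

#' Run the full staged fitting pipeline
#'
#' Reproduces the staged estimation order: (1) acquisition fits per
#' single-pathway condition give the pairing rates and per-condition gains;
#' (2) wild-type acquisition records give the gain refit under the combined
#' rule; (3) retention records give the background decay rates; (4)
#' DAN-activation records give the unpaired decay rates. Stages whose
#' records are absent from the dataset are skipped. Reversal protocols are
#' never fitted: they are predicted from the assembled parameters with
#' nothing refit.
#'
#' @inheritParams fit_acquisition
#' @param wild_rule combination rule for the wild-type gain refit.
#' @return A list with the individual `fit_result`s (`acquisition_no_null`,
#'   `acquisition_da_null`, `background`, `unpaired`, `gain`), the assembled
#'   `params` ([plasticity_params()]) and `gains` (named vector).
#' @export
staged_fit <- function(dataset, params = plasticity_params(), grid = NULL,
                       protocols = protocol_library(),
                       wild_rule = c("multiplicative", "additive"),
                       active_fraction = 0.10, refine = 2) {
  wild_rule <- match.arg(wild_rule)
  .check_dataset(dataset)
  protos <- .resolve_protocols(dataset$protocol, protocols)
  kinds <- vapply(protos, .protocol_kind, character(1))
  kind_of <- kinds[dataset$protocol]
  out <- list()
  pars <- unclass(params)
  gains <- c()

  acq <- dataset[kind_of == "acquisition", , drop = FALSE]
  for (cond in c("no_null", "da_null")) {
    if (!any(acq$condition == cond)) next
    fit <- fit_acquisition(acq, cond, grid = grid,
                           params = do.call(plasticity_params, pars),
                           protocols = protocols,
                           active_fraction = active_fraction, refine = refine)
    out[[paste0("acquisition_", cond)]] <- fit
    rate_name <- if (cond == "no_null") "a_d" else "a_n"
    pars[[rate_name]] <- fit$estimates[[rate_name]]
    gains[cond] <- fit$estimates$g
  }

  wt <- dataset[kind_of == "acquisition" & dataset$condition == "wild_type", ,
                drop = FALSE]
  if (nrow(wt)) {
    fit <- refit_gain(wt, wild_rule, do.call(plasticity_params, pars),
                      grid = grid, protocols = protocols,
                      active_fraction = active_fraction, refine = refine)
    out$gain <- fit
    gains["wild_type"] <- fit$estimates$g
  }

  ret <- dataset[kind_of == "retention", , drop = FALSE]
  if (nrow(ret)) {
    fit <- fit_background_decay(ret, do.call(plasticity_params, pars),
                                gains = gains, wild_rule = wild_rule,
                                grid = grid, protocols = protocols,
                                active_fraction = active_fraction,
                                refine = refine)
    out$background <- fit
    pars$b_d_bg <- fit$estimates$b_d_bg
    pars$b_n_bg <- fit$estimates$b_n_bg
  }

  unp <- dataset[kind_of == "dan_only", , drop = FALSE]
  if (nrow(unp)) {
    fit <- fit_unpaired(unp, do.call(plasticity_params, pars),
                        gains = gains, wild_rule = wild_rule,
                        grid = grid, protocols = protocols,
                        active_fraction = active_fraction, refine = refine)
    out$unpaired <- fit
    pars$b_d <- fit$estimates$b_d
    pars$b_n <- fit$estimates$b_n
  }

  out$params <- do.call(plasticity_params, pars)
  out$gains <- gains
  out
}
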