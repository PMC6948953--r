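# Parameter container and serialization -------------------------------------

#' Plasticity rate constants for the dopamine and nitric-oxide pathways
#'
#' Kinetic parameters of the two-pathway plasticity model of a mushroom-body
#' compartment. Each pathway (DA = dopamine, NO = nitric oxide) has
#'
#' * a pairing rate `a_*` that drives the fast eligibility variable towards 1
#'   while a Kenyon cell (KC) and the compartment's dopaminergic neuron (DAN)
#'   are coactive,
#' * an unpaired decay rate `b_*` that drives it towards 0 while the DAN is
#'   active but the KC is silent,
#' * a background decay rate `b_*_bg` for spontaneous DAN activity after
#'   training, and
#' * an expression time constant `tau_*_s` with which the slow, behaviourally
#'   expressed variable low-pass filters the fast one.
#'
#' Rates are stored in the field convention of `min^-1`; time constants in
#' seconds. Conversion to a common time unit happens once, inside the
#' propagators, so printed parameter values can be used verbatim.
#'
#' The defaults are the fitted values for optogenetic conditioning with
#' PPL1-gamma1pedc: the DA pathway learns fast (`a_d` = 4.3 min^-1) and the NO
#' pathway slowly (`a_n` = 0.96 min^-1) but with a much longer expression time
#' constant (10 min vs 30 s), which is what makes the NO-dependent memory slow
#' to appear and slow to erase.
#'
#' @param a_d,a_n pairing rates (min^-1), DA and NO pathway.
#' @param b_d,b_n unpaired-DAN decay rates (min^-1).
#' @param b_d_bg,b_n_bg background-DAN decay rates (min^-1).
#' @param tau_d_s,tau_n_s expression time constants (seconds), strictly
#'   positive.
#' @return An object of class `plasticity_params` (a named list).
#' @examples
#' p <- plasticity_params()
#' p$a_d
#' @seealso [fitted_gains()] for the matching softmax gains,
#'   [propagate_segment()] for the dynamics the rates parameterize.
#' @export
plasticity_params <- function(a_d = 4.3, a_n = 0.96,
                              b_d = 0.26, b_n = 0.16,
                              b_d_bg = 2.7e-3, b_n_bg = 1.6e-3,
                              tau_d_s = 30, tau_n_s = 600) {
  p <- list(a_d = a_d, a_n = a_n, b_d = b_d, b_n = b_n,
            b_d_bg = b_d_bg, b_n_bg = b_n_bg,
            tau_d_s = tau_d_s, tau_n_s = tau_n_s)
  .check_params(p)
  structure(p, class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("Two-pathway plasticity parameters\n")
  cat(sprintf("  pairing      a_d = %g, a_n = %g (min^-1)\n", x$a_d[1], x$a_n[1]))
  cat(sprintf("  unpaired     b_d = %g, b_n = %g (min^-1)\n", x$b_d[1], x$b_n[1]))
  cat(sprintf("  background   b_d_bg = %g, b_n_bg = %g (min^-1)\n",
              x$b_d_bg[1], x$b_n_bg[1]))
  cat(sprintf("  expression   tau_d = %g s, tau_n = %g s\n",
              x$tau_d_s[1], x$tau_n_s[1]))
  invisible(x)
}

.param_fields <- c("a_d", "a_n", "b_d", "b_n", "b_d_bg", "b_n_bg",
                   "tau_d_s", "tau_n_s")

# fields may be equal-length vectors internally (grid evaluation); the public
# constructor is documented for scalars but does not forbid vectors.
.check_params <- function(p) {
  for (f in .param_fields) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) < 1L || anyNA(v)) {
      stop("parameter '", f, "' must be numeric and non-missing", call. = FALSE)
    }
    if (any(v < 0)) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  if (any(p$tau_d_s <= 0) || any(p$tau_n_s <= 0)) {
    stop("expression time constants must be > 0", call. = FALSE)
  }
  invisible(p)
}

.param_len <- function(p) {
  max(vapply(p[.param_fields], length, integer(1)))
}

#' Fitted softmax gains
#'
#' The softmax gain `g` maps the difference in output-neuron activation
#' between the two odors to a choice probability; it was fitted separately for
#' each genotype condition and weight-combination rule. `no_null` is the
#' DA-only condition (NO synthesis blocked), `da_null` the NO-only condition
#' (dopamine-deficient); `multiplicative` and `additive` are the wild-type
#' gains refit under the respective combination rule with both pathway rates
#' held fixed.
#'
#' @return Named numeric vector with elements `no_null`, `da_null`,
#'   `multiplicative`, `additive`.
#' @export
fitted_gains <- function() {
  c(no_null = 14.8, da_null = 12.6, multiplicative = 14.3, additive = 24.6)
}

#' Read or write plasticity parameters as JSON or YAML
#'
#' The format is chosen from the file extension (`.json` vs `.yaml`/`.yml`).
#' Keys are the field names of [plasticity_params()].
#'
#' @param params a `plasticity_params` object.
#' @param path file path.
#' @return `read_params()` returns a `plasticity_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "plasticity_params"))
  x <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    stop("unrecognized parameter file extension: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("unrecognized parameter file extension: ", path, call. = FALSE)
  }
  missing <- setdiff(.param_fields, names(x))
  if (length(missing)) {
    stop("parameter file is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(plasticity_params, x[.param_fields])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code with a temporary RNG state seeded by `seed`; NULL = use the
# ambient stream untouched
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
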