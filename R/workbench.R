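# Command-line workbench ------------------------------------------------------
#
# Thin, scriptable entry points over the package functions: simulate a named
# protocol, generate a synthetic dataset, run the staged fit, and run a
# parameter-recovery study. Every command writes a manifest (config echo +
# seed + package version) next to its outputs so a run is reproducible from
# the manifest alone. Validation happens before any file is written.
# inst/cli/mbplast.R wraps run_cli() for shell use.

.write_manifest <- function(out_dir, command, config) {
  manifest <- list(command = command,
                   package = "mbplast",
                   version = as.character(utils::packageVersion("mbplast")),
                   config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Simulate a named protocol and write trajectory and PI tables
#'
#' @param protocol name of a protocol in `protocols`.
#' @param out_dir output directory (created if needed); receives
#'   `trajectory.csv` (state at every segment boundary), `pi.csv` (one row
#'   per test time) and `manifest.json`.
#' @param params a [plasticity_params()] or a parameter file path readable
#'   by [read_params()].
#' @param rule weight-combination rule of the readout.
#' @param g softmax gain; defaults to the fitted gain for `rule` (or the
#'   NO-null/DA-null gain for the single-pathway rules).
#' @param protocols named protocol list.
#' @param plot if `TRUE`, additionally writes `trajectory.png`.
#' @return Invisibly, the paths written.
#' @export
cmd_simulate <- function(protocol, out_dir, params = plasticity_params(),
                         rule = "multiplicative", g = NULL,
                         protocols = protocol_library(), plot = FALSE) {
  if (is.character(params)) params <- read_params(params)
  if (!protocol %in% names(protocols)) {
    stop("unknown protocol '", protocol, "'; available: ",
         paste(names(protocols), collapse = ", "), call. = FALSE)
  }
  g <- g %||% switch(rule,
                     da_only = fitted_gains()[["no_null"]],
                     no_only = fitted_gains()[["da_null"]],
                     fitted_gains()[[rule]])
  p <- protocols[[protocol]]
  readout <- readout_config(g, rule)
  traj <- run_schedule(p$segments, params)
  sim <- simulate_protocol(p, params, readout)
  .ensure_dir(out_dir)
  traj_path <- file.path(out_dir, "trajectory.csv")
  pi_path <- file.path(out_dir, "pi.csv")
  utils::write.csv(as.data.frame(traj), traj_path, row.names = FALSE)
  utils::write.csv(sim, pi_path, row.names = FALSE)
  paths <- c(traj_path, pi_path)
  if (isTRUE(plot)) {
    png_path <- file.path(out_dir, "trajectory.png")
    grDevices::png(png_path, width = 900, height = 500)
    plot(traj, main = p$name)
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  .write_manifest(out_dir, "simulate",
                  list(protocol = protocol, rule = rule, g = g,
                       params = unclass(params)))
  invisible(paths)
}

#' Generate a synthetic behavioral dataset from the fitted model
#'
#' Writes `dataset.csv` (+ sidecar manifest) covering the standard
#' acquisition suite, the 24 h retention design and the DAN-activation
#' design for the conditions in `readouts`.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param noise `"binomial"` or `"none"`.
#' @param n_replicates,n_flies assay dimensions.
#' @param params generating parameters.
#' @param readouts per-condition readouts (see [fitted_readouts()]).
#' @param protocols named protocol list to generate from.
#' @return Invisibly, the dataset path.
#' @export
cmd_synth <- function(out_dir, seed = 1L, noise = "binomial",
                      n_replicates = 12, n_flies = 20,
                      params = plasticity_params(),
                      readouts = fitted_readouts(),
                      protocols = protocol_library()[c(
                        "acq_1x10s", "acq_1x1min", "acq_3x1min",
                        "acq_10x1min", "decay_24h", "dan_only_5x")]) {
  cfg <- assay_config(n_flies = n_flies, n_replicates = n_replicates,
                      seed = seed, noise = noise)
  ds <- generate_dataset(protocols, params, readouts, cfg)
  .ensure_dir(out_dir)
  path <- file.path(out_dir, "dataset.csv")
  write_behavior_dataset(ds, path)
  .write_manifest(out_dir, "synth",
                  list(seed = seed, noise = noise,
                       n_replicates = n_replicates, n_flies = n_flies,
                       params = unclass(params),
                       protocols = names(protocols)))
  invisible(path)
}

#' Run the staged grid-search fit on a dataset file
#'
#' Reads a behavior dataset CSV, runs [staged_fit()] (or a single named
#' stage) and writes one JSON per fitted stage plus the final-stage loss
#' surface CSVs.
#'
#' @param dataset_file CSV path readable by [read_behavior_dataset()].
#' @param out_dir output directory.
#' @param stage `"all"` or one of `"acquisition"`, `"background"`,
#'   `"unpaired"`, `"gain"`.
#' @param wild_rule combination rule for the wild-type stage.
#' @param refine refinement stages of the grid search.
#' @param protocols named protocol list.
#' @return Invisibly, the list returned by the fitting routine.
#' @export
cmd_fit <- function(dataset_file, out_dir, stage = "all",
                    wild_rule = "multiplicative", refine = 2,
                    protocols = protocol_library()) {
  ds <- read_behavior_dataset(dataset_file)
  stage <- match.arg(stage, c("all", "acquisition", "background", "unpaired",
                              "gain"))
  fits <- if (stage == "all") {
    staged_fit(ds, protocols = protocols, wild_rule = wild_rule,
               refine = refine)
  } else if (stage == "acquisition") {
    out <- list()
    for (cond in intersect(unique(ds$condition), c("no_null", "da_null"))) {
      out[[paste0("acquisition_", cond)]] <-
        fit_acquisition(ds, cond, protocols = protocols, refine = refine)
    }
    out
  } else if (stage == "background") {
    list(background = fit_background_decay(ds, protocols = protocols,
                                           refine = refine))
  } else if (stage == "unpaired") {
    list(unpaired = fit_unpaired(ds, protocols = protocols, refine = refine))
  } else {
    list(gain = refit_gain(ds, wild_rule, protocols = protocols,
                           refine = refine))
  }
  .ensure_dir(out_dir)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "fit_result")) {
      jsonlite::write_json(
        list(stage = nm, estimates = f$estimates, loss = f$loss,
             grid_step = as.list(f$grid_step),
             flat = as.list(f$flat), n_obs = f$n_obs),
        file.path(out_dir, paste0("fit_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
      if (!is.null(f$surface)) {
        utils::write.csv(f$surface,
                         file.path(out_dir, paste0("loss_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(fits$params)) {
    write_params(fits$params, file.path(out_dir, "params_fitted.json"))
  }
  .write_manifest(out_dir, "fit",
                  list(dataset = dataset_file, stage = stage,
                       wild_rule = wild_rule, refine = refine))
  invisible(fits)
}

#' Parameter-recovery study
#'
#' Generates datasets at the fitted parameter values, refits them with the
#' staged grid search, and writes a table of generating vs recovered values.
#' In `"none"` noise mode one noiseless dataset is fit and every row is
#' checked against a one-final-grid-step tolerance; in `"binomial"` mode the
#' study repeats over `n_seeds` seeds and summary quantiles of the relative
#' error are reported. The summary also records whether the additive rule
#' predicts a weaker memory after ten pairings than after three while the
#' multiplicative rule keeps `|PI|` non-decreasing across the acquisition
#' suite.
#'
#' @param out_dir output directory; receives `recovery.csv` and
#'   `summary.json`.
#' @param seed base seed; per-repeat seeds are `seed * 1000 + repeat index`,
#'   so adding repeats never reshuffles earlier streams.
#' @param noise `"none"` or `"binomial"`.
#' @param n_seeds repeats in binomial mode.
#' @param refine refinement stages of the grid search.
#' @return Invisibly, the recovery table.
#' @export
cmd_recover <- function(out_dir, seed = 1L, noise = "none", n_seeds = 20,
                        refine = 2) {
  truth <- plasticity_params()
  gains <- fitted_gains()
  protos <- protocol_library()[c("acq_1x10s", "acq_1x1min", "acq_3x1min",
                                 "acq_10x1min", "decay_24h", "dan_only_5x")]
  n_rep <- if (noise == "none") 1L else n_seeds
  rows <- list()
  for (k in seq_len(n_rep)) {
    cfg <- assay_config(seed = seed * 1000 + k, noise = noise)
    ds <- generate_dataset(protos, truth, fitted_readouts(), cfg)
    fits <- staged_fit(ds, refine = refine)
    ests <- c(a_d = fits$acquisition_no_null$estimates$a_d,
              g_no_null = fits$acquisition_no_null$estimates$g,
              a_n = fits$acquisition_da_null$estimates$a_n,
              g_da_null = fits$acquisition_da_null$estimates$g,
              b_d_bg = fits$background$estimates$b_d_bg,
              b_n_bg = fits$background$estimates$b_n_bg,
              b_d = fits$unpaired$estimates$b_d,
              b_n = fits$unpaired$estimates$b_n,
              g_multiplicative = fits$gain$estimates$g)
    gen <- c(a_d = truth$a_d, g_no_null = gains[["no_null"]],
             a_n = truth$a_n, g_da_null = gains[["da_null"]],
             b_d_bg = truth$b_d_bg, b_n_bg = truth$b_n_bg,
             b_d = truth$b_d, b_n = truth$b_n,
             g_multiplicative = gains[["multiplicative"]])
    ok <- c(within_grid_step(fits$acquisition_no_null,
                             c(a_d = truth$a_d, g = gains[["no_null"]])),
            within_grid_step(fits$acquisition_da_null,
                             c(a_n = truth$a_n, g = gains[["da_null"]])),
            within_grid_step(fits$background,
                             c(b_d_bg = truth$b_d_bg, b_n_bg = truth$b_n_bg)),
            within_grid_step(fits$unpaired,
                             c(b_d = truth$b_d, b_n = truth$b_n)),
            within_grid_step(fits$gain, c(g = gains[["multiplicative"]])))
    rows[[k]] <- data.frame(repeat_id = k, parameter = names(gen),
                            generating = unname(gen), recovered = unname(ests),
                            rel_error = unname(abs(ests - gen) / gen),
                            within_one_grid_step = unname(ok))
  }
  tab <- do.call(rbind, rows)
  # qualitative repeated-pairing contrast between the combination rules
  suite <- protocol_library()[c("acq_1x10s", "acq_1x1min", "acq_3x1min",
                                "acq_10x1min")]
  pi_of <- function(rule, g) {
    vapply(suite, function(p) {
      simulate_protocol(p, truth, readout_config(g, rule))$pi
    }, numeric(1))
  }
  pi_add <- pi_of("additive", gains[["additive"]])
  pi_mult <- pi_of("multiplicative", gains[["multiplicative"]])
  contrast <- list(
    additive_weaker_after_10x = unname(abs(pi_add["acq_10x1min"]) <
                                         abs(pi_add["acq_3x1min"])),
    multiplicative_nondecreasing = !is.unsorted(abs(pi_mult)))
  summary <- list(
    noise = noise, n_repeats = n_rep,
    all_within_one_grid_step = all(tab$within_one_grid_step),
    rel_error_quantiles = as.list(stats::quantile(tab$rel_error,
                                                  c(0.5, 0.9, 1))),
    repeated_pairing_contrast = contrast)
  .ensure_dir(out_dir)
  utils::write.csv(tab, file.path(out_dir, "recovery.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "recover",
                  list(seed = seed, noise = noise, n_seeds = n_rep,
                       refine = refine))
  invisible(tab)
}

# minimal --key value / --key=value parser
.parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- sub("^--", "", a)
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      i <- i + 1L
    } else {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        val <- "TRUE"
        i <- i + 1L
      } else {
        val <- args[i + 1L]
        i <- i + 2L
      }
    }
    num <- suppressWarnings(as.numeric(val))
    out[[gsub("-", "_", key)]] <- if (!is.na(num)) num else val
  }
  out
}

#' Command-line dispatcher
#'
#' Subcommands: `simulate`, `synth`, `fit`, `recover`. Options are
#' `--key value` pairs matching the arguments of the corresponding `cmd_*`
#' function (e.g. `simulate --protocol acq_3x1min --out-dir out`). Returns
#' an exit status (0 on success) rather than calling `quit()`, so it is
#' testable; the installed script `inst/cli/mbplast.R` forwards the status.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: mbplast <simulate|synth|fit|recover> [--key value ...]",
                 " simulate: --protocol <name> --out-dir <dir> [--rule r] [--g g]",
                 " synth:    --out-dir <dir> [--seed s] [--noise binomial|none]",
                 " fit:      --dataset <csv> --out-dir <dir> [--stage all|...]",
                 " recover:  --out-dir <dir> [--seed s] [--noise none|binomial]",
                 sep = "\n")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    cmd <- args[1]
    opts <- .parse_cli_args(args[-1])
    switch(cmd,
      simulate = cmd_simulate(protocol = opts$protocol,
                              out_dir = opts$out_dir,
                              params = opts$params %||% plasticity_params(),
                              rule = opts$rule %||% "multiplicative",
                              g = opts$g,
                              plot = isTRUE(as.logical(opts$plot %||% FALSE))),
      synth = cmd_synth(out_dir = opts$out_dir,
                        seed = as.integer(opts$seed %||% 1),
                        noise = opts$noise %||% "binomial",
                        n_replicates = opts$n_replicates %||% 12,
                        n_flies = opts$n_flies %||% 20),
      fit = cmd_fit(dataset_file = opts$dataset, out_dir = opts$out_dir,
                    stage = opts$stage %||% "all",
                    wild_rule = opts$wild_rule %||% "multiplicative",
                    refine = opts$refine %||% 2),
      recover = cmd_recover(out_dir = opts$out_dir,
                            seed = as.integer(opts$seed %||% 1),
                            noise = opts$noise %||% "none",
                            n_seeds = opts$n_seeds %||% 20,
                            refine = opts$refine %||% 2),
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
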