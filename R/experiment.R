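# Experiment orchestration: configuration-driven sweeps chaining the
# simulator, the fitters and the error summaries, plus the two
# reproduction presets for the headline simulation results
# (macrovascular-contamination sensitivity and dispersion bias).

# model variants admissible for each simulated signal class
.allowed_models <- list(
  "D-M-" = "gkm",
  "D-M+" = c("gkm", "gkm+mvc"),
  "D+M-" = c("gkm", "gkm+disp"),
  "D+M+" = c("gkm", "gkm+mvc", "gkm+disp", "gkm+disp+mvc")
)

#' Experiment configuration
#'
#' Validates and bundles everything one sweep needs.  Model variants are
#' checked against the signal class: a model may only include a component
#' (dispersion, macrovascular) that could plausibly be needed for that
#' class, following the fitting matrix of the study design.
#'
#' @param experiment `"abv-sweep"`, `"att-sweep"`, `"dispersion-sweep"` or
#'   `"custom"`.  The named sweeps fill in the canonical grids; `"custom"`
#'   uses `grid` as given.
#' @param protocols Character vector of builtin protocol names, or a list
#'   of [asl_protocol()] objects.
#' @param signal_class Signal class code (see
#'   [normalize_signal_class()]).
#' @param models Character vector of model variants to fit.
#' @param grid Optional [condition_grid()] override.
#' @param repeats Monte-Carlo repeats per condition.
#' @param seed Root seed.
#' @param s_values Dispersion sharpness values for D+ classes; defaults to
#'   `1/0.13 * c(1, 1/2, 1/4)` for the dispersion sweep.
#' @param noiseless Simulate without noise (single repeat per condition).
#' @return An object of class `asl_experiment_config`.
#' @export
experiment_config <- function(experiment = c("abv-sweep", "att-sweep",
                                             "dispersion-sweep", "custom"),
                              protocols = c("ref-multi", "cbf-att-opt",
                                            "cbf-opt"),
                              signal_class = "D-M+",
                              models = "gkm",
                              grid = NULL, repeats = 200L, seed = 1L,
                              s_values = NULL, noiseless = FALSE) {
  experiment <- match.arg(experiment)
  cls <- normalize_signal_class(signal_class)
  bad <- setdiff(models, .allowed_models[[cls]])
  if (length(bad))
    stop("model variant(s) ", paste(bad, collapse = ", "),
         " are not in the fitting matrix for signal class ", cls,
         " (allowed: ", paste(.allowed_models[[cls]], collapse = ", "), ")",
         call. = FALSE)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  if (is.character(protocols))
    protocols <- lapply(protocols, builtin_protocol)
  if (is.null(grid)) {
    flags <- signal_class_flags(cls)
    if (experiment == "dispersion-sweep" && is.null(s_values))
      s_values <- (1 / 0.13) * c(1, 1 / 2, 1 / 4)
    if (flags$disp && is.null(s_values)) s_values <- 1 / 0.13
    vary <- if (experiment == "abv-sweep") "abv" else "att"
    grid <- condition_grid(vary, s_values = s_values,
                           repeats = repeats, seed = seed)
  }
  structure(list(experiment = experiment, protocols = protocols,
                 signal_class = cls, models = models, grid = grid,
                 repeats = repeats, seed = seed, noiseless = noiseless),
            class = "asl_experiment_config")
}

#' Run a configured experiment
#'
#' Simulates every protocol's ensemble, fits every requested model
#' variant, computes percent-error tables, and summarizes them:
#' macrovascular-sensitivity slopes for aBV sweeps, mean error-vs-ATT
#' curves (and dispersion-bias increases when several sharpness levels are
#' present) for ATT sweeps.  Deterministic given the config seed.
#'
#' @param config An [experiment_config()].
#' @param out Optional output directory; when given, error tables are
#'   written as CSV, the summary as JSON, and a provenance manifest
#'   (config fingerprint, seed, package version) is stored alongside.
#' @param progress Print per-protocol progress lines.
#' @return List with `errors` (combined error table), `summary` (data
#'   frame of slopes or bias values) and `manifest`.
#' @export
run_experiment <- function(config, out = NULL, progress = FALSE) {
  stopifnot(inherits(config, "asl_experiment_config"))
  errs <- list()
  for (prot in config$protocols) {
    ens <- simulate_ensemble(prot, config$grid, config$signal_class,
                             noiseless = config$noiseless)
    for (mv in config$models) {
      if (progress)
        message("fitting ", prot$name, " with ", mv)
      ft <- fit_ensemble(ens, prot, model_spec(mv))
      et <- error_table(ft, cbf_true = config$grid$cbf)
      et$protocol <- prot$name
      errs[[paste(prot$name, mv)]] <- et
    }
  }
  common <- Reduce(intersect, lapply(errs, names))
  errors <- do.call(rbind, c(lapply(errs, function(d)
    d[, common, drop = FALSE]), make.row.names = FALSE))
  summary_df <- .summarize_experiment(errors, config)
  manifest <- list(
    experiment = config$experiment, signal_class = config$signal_class,
    models = config$models,
    protocols = vapply(config$protocols, function(p) p$name, character(1)),
    repeats = config$repeats, seed = config$seed,
    n_conditions = nrow(config$grid$conditions),
    package_version = as.character(utils::packageVersion("pcaslsim")))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(errors, file.path(out, "errors.csv"), row.names = FALSE)
    jsonlite::write_json(summary_df, file.path(out, "summary.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(errors = errors, summary = summary_df, manifest = manifest)
}

.summarize_experiment <- function(errors, config) {
  groups <- unique(errors[, c("protocol", "variant")])
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- errors[errors$protocol == groups$protocol[i] &
                    errors$variant == groups$variant[i], ]
    if (config$grid$vary == "abv") {
      for (par in intersect(c("cbf_error_pct", "att_error_pct"), names(sub))) {
        sl <- tryCatch(mvc_sensitivity(sub, par), error = function(e) NULL)
        if (!is.null(sl))
          rows[[length(rows) + 1L]] <-
            cbind(groups[i, ], metric = "mvc_slope", sl, row.names = NULL)
      }
    } else {
      s_levels <- sort(unique(sub$s), na.last = TRUE)
      if (length(s_levels) > 1L && !anyNA(s_levels)) {
        s0 <- max(s_levels)
        for (sl in setdiff(s_levels, s0)) {
          for (par in intersect(c("cbf_error_pct", "att_error_pct"),
                                names(sub))) {
            bias <- dispersion_bias(sub[sub$s == sl, ], sub[sub$s == s0, ],
                                    parameter = par)
            rows[[length(rows) + 1L]] <- data.frame(
              groups[i, ], metric = "dispersion_bias", parameter = par,
              s = sl, s_ref = s0, value = bias, row.names = NULL)
          }
        }
      } else {
        for (par in intersect(c("cbf_error_pct", "att_error_pct"),
                              names(sub))) {
          agg <- stats::aggregate(sub[[par]], by = list(att = sub$att), mean)
          rows[[length(rows) + 1L]] <- data.frame(
            groups[i, ], metric = "mean_error_peak", parameter = par,
            value = max(agg$x), row.names = NULL)
        }
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Reproduction presets for the headline simulation results
#'
#' `reproduce_mvc_sensitivity()` runs the aBV sweep (D-M+ signals, tissue
#' ATT 1.4 s) for the three multi-PLD protocols, fits `gkm` and
#' `gkm+mvc`, and reports the CBF/ATT sensitivity slopes together with
#' the published simulation value for the CBFopt/gkm CBF slope (33.47 %
#' error per 1% aBV).  `reproduce_dispersion_bias()` runs the ATT sweep
#' on D+M- signals at sharpness s0, s0/2 and s0/4, fits `gkm`, and
#' reports the increases in peak CBF/ATT overestimation relative to s0
#' together with the published values (7.82/15.23% for CBF, 29.07/73.42%
#' for ATT).
#'
#' @param repeats Monte-Carlo repeats per condition (>= 1; the published
#'   study used 2000).
#' @param seed Root seed.
#' @param protocols Protocols to include (mvc preset).
#' @param tolerance Relative tolerance used for the pass/fail verdict
#'   column.
#' @return Data frame of measured values; rows with a published reference
#'   carry `reference` and `within_tolerance` columns.
#' @export
reproduce_mvc_sensitivity <- function(repeats = 200L, seed = 1L,
                                      protocols = c("ref-multi",
                                                    "cbf-att-opt",
                                                    "cbf-opt"),
                                      tolerance = 0.2) {
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  cfg <- experiment_config("abv-sweep", protocols = protocols,
                           signal_class = "D-M+",
                           models = c("gkm", "gkm+mvc"),
                           repeats = repeats, seed = seed)
  res <- run_experiment(cfg)
  sl <- res$summary[res$summary$metric == "mvc_slope", ]
  sl$reference <- NA_real_
  hit <- sl$protocol == "cbf-opt" & sl$variant == "gkm" &
    sl$parameter == "cbf_error_pct"
  sl$reference[hit] <- 33.47
  sl$within_tolerance <- ifelse(
    is.na(sl$reference), NA,
    abs(sl$slope - sl$reference) <= tolerance * abs(sl$reference))
  sl
}

#' @rdname reproduce_mvc_sensitivity
#' @param protocol Protocol for the dispersion preset.
#' @export
reproduce_dispersion_bias <- function(repeats = 200L, seed = 1L,
                                      protocol = "cbf-opt",
                                      tolerance = NULL) {
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  cfg <- experiment_config("dispersion-sweep", protocols = protocol,
                           signal_class = "D+M-", models = "gkm",
                           repeats = repeats, seed = seed)
  res <- run_experiment(cfg)
  bias <- res$summary[res$summary$metric == "dispersion_bias", ]
  s0 <- 1 / 0.13
  ref <- data.frame(
    parameter = rep(c("cbf_error_pct", "att_error_pct"), each = 2),
    s = rep(c(s0 / 2, s0 / 4), 2),
    reference = c(7.82, 15.23, 29.07, 73.42))
  bias <- merge(bias, ref, by = c("parameter", "s"), all.x = TRUE)
  tol_pp <- ifelse(bias$parameter == "cbf_error_pct", 3, 10)
  if (!is.null(tolerance)) tol_pp <- tolerance
  bias$within_tolerance <- ifelse(
    is.na(bias$reference), NA, abs(bias$value - bias$reference) <= tol_pp)
  bias[order(bias$parameter, -bias$s), ]
}
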