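#' Build or read a scenario-grid configuration
#'
#' A configuration bundles everything [run_grid()] needs: the generative
#' parameters (all defaults pre-filled, so an empty call reproduces the
#' standard cohort), the refusal levels/tiers/signs to cross, the analysis
#' methods and Cox model, the replicate count and the base seed.
#' `read_scenario_config()` reads the same structure from a YAML file;
#' unknown keys raise an error and missing keys fall back to the defaults.
#'
#' @param p Vector of mean patient refusal probabilities.
#' @param tiers Correlation tiers to cross (`"zero"` is kept once, since it
#'   has no direction).
#' @param signs Correlation signs to cross.
#' @param q,tier_q,sign_q Clinician refusal level and structure (scalar).
#' @param methods Analysis methods to run.
#' @param model Cox clustering treatment.
#' @param reps Replicates per scenario.
#' @param K,J Clusters and cluster size.
#' @param alpha Significance level.
#' @param recruitment_method 1 or 2 (metadata carried into results).
#' @param base_seed Integer seed; scenario sub-seeds derive from it.
#' @param ... Further arguments to [cohort_params()] (e.g. `beta`,
#'   `sigma2_u`, `lambda_c`).
#' @return A list of class `cmrct_config`.
#' @examples
#' scenario_config(p = c(0.1, 0.2), tiers = c("zero", "high"), reps = 10)
#' @export
scenario_config <- function(p = c(0.1, 0.2, 0.3),
                            tiers = c("zero", "low", "medium", "high"),
                            signs = c("negative", "positive"),
                            q = 0, tier_q = "zero", sign_q = "negative",
                            methods = c("itt", "pp", "2sps", "2sri"),
                            model = "lognormal", reps = 1000,
                            K = 25L, J = 620L, alpha = 0.05,
                            recruitment_method = 1, base_seed = 1, ...) {
  structure(list(p = p, tiers = tiers, signs = signs,
                 q = q, tier_q = tier_q, sign_q = sign_q,
                 methods = methods, model = model, reps = reps,
                 alpha = alpha, recruitment_method = recruitment_method,
                 base_seed = base_seed,
                 params = c(list(K = K, J = J), list(...))),
            class = "cmrct_config")
}

#' @rdname scenario_config
#' @param path Path to a YAML configuration file.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  known <- c(setdiff(known, "..."), names(formals(cohort_params)))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(scenario_config, raw)
}

#' Run manifest for a grid
#'
#' Records what produced a result table: a hash of the configuration, the
#' base seed, the package version and the row count.  Two runs with
#' identical manifests produce identical tables.
#'
#' @param config A `cmrct_config`.
#' @param results The grid result table.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, results, path = NULL) {
  cfg_txt <- paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n")
  manifest <- list(
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_txt) *
                                        seq_along(utf8ToInt(cfg_txt)) %% 2^28)),
    base_seed = config$base_seed,
    package_version = as.character(utils::packageVersion("cmrctsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_rows = nrow(results),
    methods = config$methods, model = config$model, reps = config$reps)
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}

#' Bias and power panels for a grid result
#'
#' Recreates the standard two-panel display of a refusal-scenario grid: one
#' panel of percentage bias and one of power, each against the mean refusal
#' probability with one line per analysis method and one facet per
#' correlation tier.  The dashed reference line in the power panel marks the
#' power the trial was designed for.
#'
#' @param results A [run_grid()] result table.
#' @param expected_power Reference power drawn in the power panel.
#' @param path Optional directory; when given the two panels are written as
#'   `bias.png` and `power.png`.
#' @return A list with ggplot objects `bias` and `power` (invisibly when
#'   written).  An empty table returns an empty list with a warning.
#' @export
render_report <- function(results, expected_power = 0.8, path = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    warning("empty results table: nothing to report")
    return(list())
  }
  results$setting <- paste0(results$tier_p, " (", results$sign_p, ")")
  bias <- ggplot2::ggplot(results,
                          ggplot2::aes(x = p, y = pct_bias, colour = method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~setting) +
    ggplot2::labs(x = "mean patient refusal probability",
                  y = "percentage bias of the log hazard ratio",
                  colour = "method") +
    ggplot2::theme_bw()
  power <- ggplot2::ggplot(results,
                           ggplot2::aes(x = p, y = power, colour = method)) +
    ggplot2::geom_hline(yintercept = expected_power, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~setting) +
    ggplot2::labs(x = "mean patient refusal probability",
                  y = "empirical power", colour = "method") +
    ggplot2::theme_bw()
  out <- list(bias = bias, power = power)
  if (!is.null(path)) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    ggplot2::ggsave(file.path(path, "bias.png"), bias, width = 8, height = 5)
    ggplot2::ggsave(file.path(path, "power.png"), power, width = 8, height = 5)
    return(invisible(out))
  }
  out
}
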