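#' Replicate a scenario and summarise bias, error and power
#'
#' Runs `reps` independent replicates of one scenario.  Each replicate draws
#' a fresh cohort (random effects, risks, refusal probabilities), simulates
#' one trial from it, and applies the requested analysis methods.  Per
#' replicate the log-hazard-ratio estimate and its naive Wald p-value are
#' recorded; [summarize_replicates()] then computes, per method, the mean
#' estimate, percentage bias with a 95% confidence interval, the empirical
#' standard error (SD of the replicate estimates), the standard error of the
#' mean, and the power (fraction of p-values below `alpha`).
#'
#' Replicates in which a fit degenerates (e.g. an arm without events) are
#' counted and excluded from the summaries; a scenario with more than 20%
#' such replicates for any method is flagged invalid.
#'
#' @param params A [cohort_params()] object (its `K` sets the trial size).
#' @param spec A [refusal_spec()] object.
#' @param reps Number of replicates.
#' @param methods Subset of `c("itt", "pp", "2sps", "2sri")`.
#' @param model Cox clustering treatment for all methods.
#' @param base_seed Integer seed from which one sub-seed per replicate is
#'   drawn; the whole run is reproducible given `base_seed`.
#' @param alpha Significance level for the power count.
#' @param recruitment_method Metadata tag, 1 (sample size ignores refusal)
#'   or 2 (refusal factored in); carried into the result table.
#' @return An object of class `cmrct_scenario_result`: the per-method
#'   summary data frame in `$summary`, the per-replicate estimates in
#'   `$replicates`, plus `$params`, `$spec` and `$invalid`.
#' @examples
#' params <- cohort_params(J = 80, K = 10, lambda_c = 8)
#' res <- run_scenario(params, refusal_spec(p = 0.2, tier_p = "high"),
#'                     reps = 20, methods = c("itt", "2sri"),
#'                     model = "marginal", base_seed = 1)
#' res$summary
#' @export
run_scenario <- function(params, spec, reps = 1000,
                         methods = c("itt", "pp", "2sps", "2sri"),
                         model = "lognormal", base_seed = 1, alpha = 0.05,
                         recruitment_method = 1) {
  stopifnot(reps >= 2)
  methods <- tolower(methods)
  funs <- lapply(methods, method_fun)
  set.seed(check_seed(base_seed))
  rep_seeds <- sample.int(2147483647L, reps)
  coef <- pval <- matrix(NA_real_, nrow = reps, ncol = length(methods),
                         dimnames = list(NULL, methods))
  conv <- matrix(FALSE, nrow = reps, ncol = length(methods),
                 dimnames = list(NULL, methods))
  for (j in seq_len(reps)) {
    set.seed(rep_seeds[j])
    cohort <- simulate_cohort(params, spec)
    trial <- simulate_trial(cohort, params)
    for (m in seq_along(methods)) {
      est <- funs[[m]](trial, model = model)
      if (isTRUE(est$converged)) {
        coef[j, m] <- est$coef
        pval[j, m] <- est$pvalue
        conv[j, m] <- TRUE
      }
    }
  }
  replicates <- data.frame(rep = rep(seq_len(reps), length(methods)),
                           method = rep(toupper(methods), each = reps),
                           coef = as.vector(coef), pvalue = as.vector(pval),
                           converged = as.vector(conv))
  summary <- summarize_replicates(coef, pval, beta_true = params$beta,
                                  alpha = alpha)
  summary <- cbind(data.frame(p = spec$p, q = spec$q,
                              tier_p = spec$tier_p, sign_p = spec$sign_p,
                              model = model,
                              recruitment_method = recruitment_method,
                              K = params$K, reps = reps),
                   summary)
  invalid <- any(summary$n_converged < 0.8 * reps)
  structure(list(summary = summary, replicates = replicates,
                 params = params, spec = spec, invalid = invalid),
            class = "cmrct_scenario_result")
}

#' @export
print.cmrct_scenario_result <- function(x, ...) {
  cat(sprintf("cmRCT scenario: p = %.2g (%s, %s), q = %.2g, %s model, %d reps%s\n",
              x$spec$p, x$spec$tier_p, x$spec$sign_p, x$spec$q,
              x$summary$model[1], x$summary$reps[1],
              if (x$invalid) "  [FLAGGED INVALID: >20% non-converged]" else ""))
  print(x$summary[c("method", "mean_beta", "pct_bias", "pct_bias_lo",
                    "pct_bias_hi", "emp_se", "power", "n_converged")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarise per-replicate estimates into bias and power
#'
#' For each method computes the mean estimate over converged replicates,
#' the percentage bias `100 * (mean - beta) / beta`, its 95% confidence
#' interval from the standard error of the mean (`emp_se / sqrt(n)`), the
#' empirical standard error (SD of the replicate estimates), and the power
#' (fraction of naive Wald p-values below `alpha`).
#'
#' @param coef Matrix of replicate estimates, one column per method (a
#'   single vector is accepted).
#' @param pval Matching matrix of p-values.
#' @param beta_true True log hazard ratio.
#' @param alpha Significance level.
#' @return A data frame with one row per method.
#' @examples
#' summarize_replicates(cbind(itt = c(-0.30, -0.34)),
#'                      cbind(itt = c(0.01, 0.20)), beta_true = -0.32)
#' @export
summarize_replicates <- function(coef, pval, beta_true, alpha = 0.05) {
  coef <- as.matrix(coef); pval <- as.matrix(pval)
  methods <- colnames(coef)
  if (is.null(methods)) methods <- paste0("m", seq_len(ncol(coef)))
  out <- lapply(seq_len(ncol(coef)), function(m) {
    b <- coef[, m]; p <- pval[, m]
    ok <- is.finite(b) & is.finite(p)
    n <- sum(ok)
    if (n < 2)
      return(data.frame(method = toupper(methods[m]), mean_beta = NA_real_,
                        pct_bias = NA_real_, pct_bias_lo = NA_real_,
                        pct_bias_hi = NA_real_, emp_se = NA_real_,
                        se_of_mean = NA_real_, power = NA_real_,
                        n_converged = n))
    b <- b[ok]; p <- p[ok]
    mean_beta <- mean(b)
    emp_se <- stats::sd(b)
    se_mean <- emp_se / sqrt(n)
    ci <- range(100 * ((mean_beta + c(-1.96, 1.96) * se_mean) - beta_true) /
                  beta_true)
    data.frame(method = toupper(methods[m]), mean_beta = mean_beta,
               pct_bias = 100 * (mean_beta - beta_true) / beta_true,
               pct_bias_lo = ci[1], pct_bias_hi = ci[2],
               emp_se = emp_se, se_of_mean = se_mean,
               power = mean(p < alpha), n_converged = n)
  })
  do.call(rbind, out)
}

#' Run a grid of scenarios
#'
#' Expands the Cartesian product of the configured refusal levels, tiers and
#' signs, maps one deterministic sub-seed to each scenario, and runs
#' [run_scenario()] on each.  With `out_dir` set, per-scenario summaries are
#' written incrementally as tab-separated files and already-completed
#' scenarios are skipped on a rerun, so an interrupted grid resumes.
#'
#' @param config A configuration list as returned by
#'   [scenario_config()] / [read_scenario_config()].
#' @param out_dir Optional directory for incremental per-scenario output.
#' @param verbose Print one line per scenario?
#' @return A data frame with one row per scenario and method (class
#'   `cmrct_grid_result`), with the full per-scenario objects in attribute
#'   `"scenarios"`.
#' @examples
#' cfg <- scenario_config(p = c(0, 0.2), tiers = "zero", signs = "negative",
#'                        reps = 5, K = 8, J = 60, lambda_c = 8,
#'                        methods = "itt", model = "marginal")
#' run_grid(cfg)
#' @export
run_grid <- function(config, out_dir = NULL, verbose = FALSE) {
  cfg <- config
  grid <- expand.grid(p = cfg$p, tier = cfg$tiers, sign = cfg$signs,
                      stringsAsFactors = FALSE)
  # the zero tier has no direction: keep a single copy
  zero <- grid$tier == "zero"
  grid <- rbind(grid[zero & grid$sign == grid$sign[1], , drop = FALSE],
                grid[!zero, , drop = FALSE])
  set.seed(check_seed(cfg$base_seed))
  seeds <- sample.int(2147483647L, nrow(grid))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  params <- do.call(cohort_params, cfg$params)
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tag <- sprintf("p%s_%s_%s", grid$p[i], grid$tier[i], grid$sign[i])
    f <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".tsv"))
    if (!is.null(f) && file.exists(f)) {
      results[[i]] <- utils::read.table(f, header = TRUE, sep = "\t")
      next
    }
    spec <- refusal_spec(p = grid$p[i], q = cfg$q,
                         tier_p = grid$tier[i], sign_p = grid$sign[i],
                         tier_q = cfg$tier_q, sign_q = cfg$sign_q)
    res <- run_scenario(params, spec, reps = cfg$reps, methods = cfg$methods,
                        model = cfg$model, base_seed = seeds[i],
                        alpha = cfg$alpha,
                        recruitment_method = cfg$recruitment_method)
    results[[i]] <- res$summary
    if (!is.null(f))
      utils::write.table(res$summary, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    if (verbose)
      cat(sprintf("[%d/%d] %s done\n", i, nrow(grid), tag))
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  class(out) <- c("cmrct_grid_result", "data.frame")
  out
}
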