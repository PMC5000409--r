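#' Analysis methods for one simulated trial
#'
#' The four methods target the effect of *accepting* the intervention but
#' differ in how they handle refusal:
#'
#' * **ITT** (`estimate_itt`) — Cox fit on the random allocation `z`,
#'   ignoring uptake; attenuated towards zero by refusal (dilution bias).
#' * **PP** (`estimate_pp`) — drops intervention-arm refusers and fits on
#'   treatment received `x`; subject to selection bias when refusal is
#'   correlated with risk.
#' * **2SPS** (`estimate_2sps`) — two-stage predictor substitution: replaces
#'   `x` by its first-stage fitted value.  With a binary instrument and a
#'   linear first stage this equals the ITT coefficient divided by the
#'   intervention-arm acceptance rate.
#' * **2SRI** (`estimate_2sri`) — two-stage residual inclusion: fits on `x`
#'   plus the first-stage residual, which absorbs the confounding induced by
#'   risk-correlated refusal.
#'
#' Each returns a `cmrct_estimate`: `method`, `coef` (log hazard ratio for
#' the method's treatment quantity), `se_naive` (second-stage model SE),
#' `se_bootstrap` (`NA` unless computed via [bootstrap_se()]), `pvalue`
#' (naive Wald, used by the power engine), `n_used`, `converged`, and the
#' underlying `fit`.  A replicate in which an arm has no events is returned
#' with `converged = FALSE` instead of raising, so the replication engine
#' can count and exclude it.
#'
#' @param trial A [simulate_trial()] data frame.
#' @param model Cox clustering treatment passed to [fit_cox()]:
#'   `"lognormal"` (default), `"marginal"` or `"gamma"`.
#' @return An object of class `cmrct_estimate`.
#' @name estimators
NULL

method_estimate <- function(method, fit, covariate, n_used) {
  structure(list(method = method,
                 coef = unname(fit$coef[covariate]),
                 se_naive = unname(fit$se[covariate]),
                 se_bootstrap = NA_real_,
                 pvalue = unname(fit$pvalue[covariate]),
                 n_used = n_used, converged = fit$converged, fit = fit),
            class = "cmrct_estimate")
}

estimate_failed <- function(method, n_used, msg) {
  structure(list(method = method, coef = NA_real_, se_naive = NA_real_,
                 se_bootstrap = NA_real_, pvalue = NA_real_,
                 n_used = n_used, converged = FALSE, fit = NULL,
                 message = msg),
            class = "cmrct_estimate")
}

#' @export
print.cmrct_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: log HR = %.4f (HR %.3f), naive SE %.4f, p = %.3g\n",
              x$method, x$coef, exp(x$coef), x$se_naive, x$pvalue))
  if (!is.na(x$se_bootstrap))
    cat(sprintf("  cluster-bootstrap SE: %.4f\n", x$se_bootstrap))
  cat(sprintf("  n used: %d%s\n", x$n_used,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

arm_has_events <- function(trial, arm) {
  tapply(1L - trial$c, arm, sum)
}

#' @rdname estimators
#' @export
estimate_itt <- function(trial, model = "lognormal") {
  ev <- arm_has_events(trial, trial$z)
  if (length(ev) < 2L || any(ev == 0))
    return(estimate_failed("ITT", nrow(trial), "an allocation arm has no events"))
  method_estimate("ITT", fit_cox(trial, "z", model), "z", nrow(trial))
}

#' @rdname estimators
#' @export
estimate_pp <- function(trial, model = "lognormal") {
  keep <- !(trial$z == 1 & trial$x == 0)
  sub <- trial[keep, , drop = FALSE]
  ev <- arm_has_events(sub, sub$x)
  if (length(ev) < 2L || any(ev == 0))
    return(estimate_failed("PP", nrow(sub), "a treatment group has no events"))
  method_estimate("PP", fit_cox(sub, "x", model), "x", nrow(sub))
}

#' First-stage instrumental-variable regression
#'
#' Least-squares regression of treatment received on treatment allocation
#' (the instrument).  With a binary instrument the fit is saturated: the
#' fitted value is 0 for controls and the intervention-arm acceptance rate
#' for allocated subjects; residuals sum to zero within each arm.
#'
#' @param trial A trial data frame with columns `z` and `x`.
#' @return A list with `xhat`, `residual` (per subject) and `acceptance`
#'   (the intervention-arm acceptance rate).
#' @export
first_stage <- function(trial) {
  if (!any(trial$z == 1))
    stop("instrument has no variation: no intervention-arm subjects",
         call. = FALSE)
  fs <- stats::lm(x ~ z, data = trial)
  list(xhat = unname(stats::fitted(fs)),
       residual = unname(stats::residuals(fs)),
       acceptance = mean(trial$x[trial$z == 1]))
}

#' @rdname estimators
#' @export
estimate_2sps <- function(trial, model = "lognormal") {
  ev <- arm_has_events(trial, trial$z)
  if (length(ev) < 2L || any(ev == 0))
    return(estimate_failed("2SPS", nrow(trial), "an allocation arm has no events"))
  fs <- first_stage(trial)
  if (fs$acceptance == 0)
    return(estimate_failed("2SPS", nrow(trial), "no uptake in the intervention arm"))
  trial$xhat <- fs$xhat
  method_estimate("2SPS", fit_cox(trial, "xhat", model), "xhat", nrow(trial))
}

#' @rdname estimators
#' @export
estimate_2sri <- function(trial, model = "lognormal") {
  ev <- arm_has_events(trial, trial$z)
  if (length(ev) < 2L || any(ev == 0))
    return(estimate_failed("2SRI", nrow(trial), "an allocation arm has no events"))
  fs <- first_stage(trial)
  trial$resid <- fs$residual
  if (stats::var(fs$residual) < 1e-12) {
    # full compliance: the residual column is identically zero and is
    # dropped, reducing 2SRI to the fit on x alone (= ITT here)
    if (stats::var(trial$x) == 0)
      return(estimate_failed("2SRI", nrow(trial), "treatment received is constant"))
    est <- method_estimate("2SRI", fit_cox(trial, "x", model), "x", nrow(trial))
    est$residual_dropped <- TRUE
    return(est)
  }
  est <- method_estimate("2SRI", fit_cox(trial, c("x", "resid"), model),
                         "x", nrow(trial))
  est$residual_dropped <- FALSE
  est
}

method_fun <- function(method) {
  switch(tolower(method),
         itt = estimate_itt, pp = estimate_pp,
         `2sps` = estimate_2sps, `2sri` = estimate_2sri,
         stop("unknown method: ", method, call. = FALSE))
}

#' Cluster-bootstrap standard error for a two-stage estimator
#'
#' The naive second-stage standard errors of 2SPS/2SRI ignore the
#' first-stage estimation error, so a nonparametric bootstrap is used:
#' clusters (the randomisation unit) are resampled with replacement and both
#' stages are re-run on each resample.  The returned standard error is the
#' standard deviation of the resampled coefficients.
#'
#' @param trial A trial data frame.
#' @param estimator `"2sps"` or `"2sri"` (any method is accepted).
#' @param B Number of bootstrap resamples (at least 50).
#' @param model Cox clustering treatment for the second stage.
#' @param seed Optional integer seed.
#' @return The bootstrap standard error (a single number); resamples whose
#'   fit fails are skipped, with the usable count in attribute `"B_used"`.
#' @export
bootstrap_se <- function(trial, estimator = c("2sps", "2sri"), B = 200,
                         model = "lognormal", seed = NULL) {
  if (is.character(estimator)) estimator <- match.arg(estimator)
  f <- method_fun(estimator)
  if (B < 50) stop("`B` must be at least 50", call. = FALSE)
  if (!is.null(seed)) set.seed(check_seed(seed))
  cl_ids <- unique(trial$cluster)
  K <- length(cl_ids)
  rows <- split(seq_len(nrow(trial)), trial$cluster)
  coefs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample.int(K, K, replace = TRUE)
    idx <- unlist(rows[pick], use.names = FALSE)
    boot <- trial[idx, , drop = FALSE]
    # relabel so each resampled copy of a cluster is its own cluster
    boot$cluster <- rep.int(seq_len(K),
                            vapply(rows[pick], length, integer(1)))
    est <- f(boot, model = model)
    if (isTRUE(est$converged)) coefs[b] <- est$coef
  }
  used <- sum(!is.na(coefs))
  if (used < 2) stop("bootstrap failed: fewer than 2 usable resamples",
                     call. = FALSE)
  structure(stats::sd(coefs, na.rm = TRUE), B_used = used)
}
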