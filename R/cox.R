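#' Fit a Cox proportional-hazards model to clustered trial data
#'
#' Fits the outcome model used by all four analysis methods, with one of
#' three treatments of the clustering:
#'
#' * `"marginal"` — ordinary partial likelihood with a cluster-grouped
#'   robust (sandwich) variance; the hazard ratio is population-averaged.
#' * `"lognormal"` — normal random intercept per cluster on the log-hazard
#'   scale (a lognormal frailty), fitted by penalised partial likelihood;
#'   this matches the generating model, and the hazard ratio is conditional
#'   (within-cluster).
#' * `"gamma"` — multiplicative gamma frailty with mean 1, deliberately
#'   misspecified for data generated with normal random effects.
#'
#' The event indicator is `1 - c` (in the trial table `c = 1` means
#' censored).  Ties are handled by the Breslow approximation; event times
#' are continuous so ties have probability zero.
#'
#' @param data A trial data frame with columns `y`, `c`, `cluster`, and the
#'   covariate columns named in `covariates`.
#' @param covariates Character vector of covariate column names; the first
#'   is the treatment quantity whose log hazard ratio is reported first.
#' @param model `"marginal"`, `"lognormal"` or `"gamma"`.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return An object of class `cmrct_coxfit`: a list with elements `coef`,
#'   `se` (robust for the marginal model), `pvalue` (Wald), `frailty_variance`
#'   (`NA` for the marginal model), `loglik`, `converged`, `n_events`, `n`,
#'   `model`.  A fit that fails or degenerates returns `converged = FALSE`
#'   with `NA` estimates rather than raising an error.
#' @examples
#' params <- cohort_params(J = 80, K = 10, lambda_c = 8)
#' trial <- simulate_trial(simulate_cohort(params, seed = 1), params, seed = 2)
#' fit_cox(trial, "z", model = "lognormal")
#' @export
fit_cox <- function(data, covariates, model = c("lognormal", "marginal", "gamma"),
                    ties = "breslow") {
  model <- match.arg(model)
  stopifnot(all(c("y", "c", "cluster", covariates) %in% names(data)))
  df <- as.data.frame(data)[c("y", "c", "cluster", covariates)]
  df$event <- 1L - df$c
  n_events <- sum(df$event)
  if (n_events < 2L)
    stop("need at least 2 events to fit a Cox model", call. = FALSE)
  for (v in covariates)
    if (stats::var(df[[v]]) == 0)
      stop("covariate `", v, "` is constant", call. = FALSE)
  terms <- switch(model,
                  marginal  = "cluster(cluster)",
                  lognormal = c("frailty.gaussian(cluster)",
                                "frailty.gaussian(cluster, sparse = FALSE)"),
                  gamma     = c("frailty.gamma(cluster)",
                                "frailty.gamma(cluster, sparse = FALSE)"))
  # generous iteration limits: the outer profile search over the frailty
  # variance occasionally probes large values whose inner penalised fit
  # needs more than the default number of Newton steps
  ctrl <- survival::coxph.control(iter.max = 50, outer.max = 30)
  fit <- NULL
  for (term in terms) {
    # the sparse frailty algorithm occasionally diverges in its outer
    # variance search; the dense parameterisation is the fallback
    fml <- stats::as.formula(
      paste0("Surv(y, event) ~ ", paste(covariates, collapse = " + "),
             " + ", term))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = df, ties = ties,
                                       control = ctrl,
                                       x = FALSE, y = FALSE, model = FALSE)),
      error = function(e) e)
    if (!inherits(fit, "error") &&
        all(is.finite(fit$coefficients[covariates])) &&
        all(sqrt(diag(as.matrix(fit$var)))[match(covariates,
                                                 names(fit$coefficients))] > 0))
      break
  }
  if (inherits(fit, "error"))
    return(coxfit_failed(covariates, model, n_events, nrow(df),
                         conditionMessage(fit)))
  coef <- fit$coefficients[covariates]
  # For penalised (frailty) fits fit$var covers the estimated coefficients;
  # for the marginal model it is the cluster-grouped sandwich estimator.
  se_all <- sqrt(diag(as.matrix(fit$var)))[seq_along(fit$coefficients)]
  names(se_all) <- names(fit$coefficients)
  se <- se_all[covariates]
  se_naive <- if (!is.null(fit$naive.var))
    sqrt(diag(as.matrix(fit$naive.var)))[match(covariates, names(fit$coefficients))]
  else se
  theta <- if (model == "marginal") NA_real_ else {
    h <- fit$history[[1L]]
    th <- h$theta
    if (is.null(th)) th <- utils::tail(h$thetas, 1L)
    as.numeric(th)
  }
  ok <- all(is.finite(coef)) && all(is.finite(se)) && all(se > 0) &&
    all(abs(coef) < 15)
  structure(list(coef = coef, se = se, se_naive = se_naive,
                 pvalue = 2 * stats::pnorm(-abs(coef / se)),
                 frailty_variance = theta,
                 loglik = utils::tail(fit$loglik, 1L),
                 converged = ok, n_events = n_events, n = nrow(df),
                 model = model, message = NULL),
            class = "cmrct_coxfit")
}

coxfit_failed <- function(covariates, model, n_events, n, msg) {
  k <- length(covariates)
  structure(list(coef = stats::setNames(rep(NA_real_, k), covariates),
                 se = stats::setNames(rep(NA_real_, k), covariates),
                 se_naive = rep(NA_real_, k),
                 pvalue = rep(NA_real_, k),
                 frailty_variance = NA_real_, loglik = NA_real_,
                 converged = FALSE, n_events = n_events, n = n,
                 model = model, message = msg),
            class = "cmrct_coxfit")
}

#' @export
print.cmrct_coxfit <- function(x, ...) {
  cat(sprintf("Cox fit (%s clustering), n = %d, events = %d%s\n",
              x$model, x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = x$se,
                    p = x$pvalue, check.names = FALSE)
  print(round(tab, 4))
  if (!is.na(x$frailty_variance))
    cat(sprintf("frailty variance: %.4f\n", x$frailty_variance))
  invisible(x)
}

#' @rdname fit_cox
#' @param data,covariates,ties As in `fit_cox()`.
#' @export
fit_cox_marginal <- function(data, covariates = "z", ties = "breslow")
  fit_cox(data, covariates, model = "marginal", ties = ties)

#' @rdname fit_cox
#' @export
fit_cox_lognormal_frailty <- function(data, covariates = "z", ties = "breslow")
  fit_cox(data, covariates, model = "lognormal", ties = ties)

#' @rdname fit_cox
#' @export
fit_cox_gamma_frailty <- function(data, covariates = "z", ties = "breslow")
  fit_cox(data, covariates, model = "gamma", ties = ties)
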