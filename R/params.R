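#' Generative parameters for a simulated cmRCT cohort
#'
#' Container for the constants that drive the data-generating model: Weibull
#' shape/scale pairs for the time to a cardiovascular (CVD) event and the time
#' to death, the variances of the individual- and cluster-level normal random
#' effects that act multiplicatively on both hazards, the intervention
#' log-hazard ratio, the cluster size and count, and the administrative
#' follow-up horizon.
#'
#' The defaults describe a cohort of patients at high risk of CVD: cluster
#' size `J = 620` (an average UK practice's eligible patients), event-time
#' Weibull shape 1.2 and scale 36 years, mortality shape 1.2 and scale 55
#' years, random-effect variances `(0.6, 0.2)`, intervention effect
#' `beta = -0.32` on the log-hazard scale and 3 years of follow-up.  Under
#' these defaults the counterfactual 10-year CVD risk has mean 21.1% and
#' standard deviation 8.6%, and the latent event and death times have
#' correlation about 0.25 through the shared random effects.
#'
#' @param J Subjects per cluster (all clusters the same size).
#' @param K Number of clusters.
#' @param gamma_c,lambda_c Weibull shape and scale (years) for the CVD event
#'   time.
#' @param gamma_m,lambda_m Weibull shape and scale (years) for the mortality
#'   time.
#' @param sigma2_eps Variance of the individual-level random effect.
#' @param sigma2_u Variance of the cluster-level random effect.
#' @param beta Intervention effect: log hazard ratio applied to the CVD
#'   hazard of subjects who receive the intervention.
#' @param T_max Administrative censoring horizon in years.
#' @param icc_label Optional metadata tag naming the intra-cluster
#'   correlation setting; filled automatically for the two standard variance
#'   pairs `(0.6, 0.2)` ("0.025") and `(0.57, 0.27)` ("0.05").
#'
#' @return An object of class `cmrct_params` (a named list).
#' @examples
#' cohort_params()
#' cohort_params(sigma2_eps = 0.57, sigma2_u = 0.27)
#' @export
cohort_params <- function(J = 620L, K = 25L,
                          gamma_c = 1.2, lambda_c = 36,
                          gamma_m = 1.2, lambda_m = 55,
                          sigma2_eps = 0.6, sigma2_u = 0.2,
                          beta = -0.32, T_max = 3,
                          icc_label = NULL) {
  J <- as.integer(J); K <- as.integer(K)
  stopifnot(is.finite(J), is.finite(K), J >= 2L, K >= 2L)
  for (nm in c("gamma_c", "lambda_c", "gamma_m", "lambda_m", "T_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number", call. = FALSE)
  }
  for (nm in c("sigma2_eps", "sigma2_u")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
  }
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (is.null(icc_label)) {
    icc_label <- if (isTRUE(all.equal(c(sigma2_eps, sigma2_u), c(0.6, 0.2)))) {
      "0.025"
    } else if (isTRUE(all.equal(c(sigma2_eps, sigma2_u), c(0.57, 0.27)))) {
      "0.05"
    } else NA_character_
  }
  structure(list(J = J, K = K,
                 gamma_c = gamma_c, lambda_c = lambda_c,
                 gamma_m = gamma_m, lambda_m = lambda_m,
                 sigma2_eps = sigma2_eps, sigma2_u = sigma2_u,
                 beta = beta, T_max = T_max, icc_label = icc_label),
            class = "cmrct_params")
}

#' @export
print.cmrct_params <- function(x, ...) {
  cat("cmRCT cohort parameters\n")
  cat(sprintf("  clusters K = %d, cluster size J = %d (N = %d)\n",
              x$K, x$J, x$K * x$J))
  cat(sprintf("  CVD time:   Weibull(shape %.3g, scale %.3g y)\n",
              x$gamma_c, x$lambda_c))
  cat(sprintf("  mortality:  Weibull(shape %.3g, scale %.3g y)\n",
              x$gamma_m, x$lambda_m))
  cat(sprintf("  random effects: sigma2_eps = %.3g, sigma2_u = %.3g (ICC tag %s)\n",
              x$sigma2_eps, x$sigma2_u, x$icc_label))
  cat(sprintf("  intervention log HR beta = %.3g, follow-up T_max = %.3g y\n",
              x$beta, x$T_max))
  invisible(x)
}

#' Refusal structure: mean levels and correlation with risk
#'
#' Describes how the probability of a patient refusing the offered
#' intervention (`p`), and of a clinician refusing to offer it (`q`), vary
#' across the cohort.  Individual probabilities are assigned by ranking
#' subjects on their counterfactual 10-year risk and spreading probabilities
#' linearly between a lower and upper limit chosen by `tier`:
#'
#' * `"zero"`   — `(LL, UL) = (p, p)`: no correlation with risk,
#' * `"low"`    — `(2p/3, 4p/3)`,
#' * `"medium"` — `(p/3, 5p/3)`,
#' * `"high"`   — `(0, 2p)`.
#'
#' `sign = "positive"` gives higher refusal to higher-risk subjects,
#' `"negative"` the reverse.  Every tier is symmetric about the mean, so the
#' cohort mean refusal always equals `p` (resp. `q`) exactly.
#'
#' @param p,q Mean patient / clinician refusal probabilities in `[0, 1]`.
#' @param tier_p,tier_q Correlation tier, one of `"zero"`, `"low"`,
#'   `"medium"`, `"high"`.
#' @param sign_p,sign_q Direction of the correlation with risk,
#'   `"positive"` or `"negative"`.
#' @return An object of class `cmrct_refusal` (a named list).
#' @examples
#' refusal_spec(p = 0.2, tier_p = "high", sign_p = "negative")
#' @export
refusal_spec <- function(p = 0, q = 0,
                         tier_p = "zero", tier_q = "zero",
                         sign_p = "negative", sign_q = "negative") {
  tier_p <- match.arg(tier_p, c("zero", "low", "medium", "high"))
  tier_q <- match.arg(tier_q, c("zero", "low", "medium", "high"))
  sign_p <- match.arg(sign_p, c("positive", "negative"))
  sign_q <- match.arg(sign_q, c("positive", "negative"))
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(q), length(q) == 1L, q >= 0, q <= 1)
  # limits must stay inside [0, 1]; only the upper limit can escape
  for (side in list(c(p, tier_p, "p"), c(q, tier_q, "q"))) {
    lim <- refusal_limits(as.numeric(side[1]), side[2])
    if (lim[2] > 1 + 1e-12)
      stop("tier '", side[2], "' puts the upper refusal limit above 1 for ",
           side[3], " = ", side[1], call. = FALSE)
  }
  structure(list(p = p, q = q, tier_p = tier_p, tier_q = tier_q,
                 sign_p = sign_p, sign_q = sign_q),
            class = "cmrct_refusal")
}

#' @export
print.cmrct_refusal <- function(x, ...) {
  cat("cmRCT refusal specification\n")
  cat(sprintf("  patient:   mean p = %.3g, tier %s, sign %s\n",
              x$p, x$tier_p, x$sign_p))
  cat(sprintf("  clinician: mean q = %.3g, tier %s, sign %s\n",
              x$q, x$tier_q, x$sign_q))
  invisible(x)
}

#' Lower and upper refusal limits for a correlation tier
#'
#' @param mean Mean refusal probability.
#' @param tier One of `"zero"`, `"low"`, `"medium"`, `"high"`.
#' @return Numeric vector `c(LL, UL)`.
#' @examples
#' refusal_limits(0.3, "high")  # c(0, 0.6)
#' @export
refusal_limits <- function(mean, tier) {
  tier <- match.arg(tier, c("zero", "low", "medium", "high"))
  switch(tier,
         zero   = c(mean, mean),
         low    = c(2 * mean / 3, 4 * mean / 3),
         medium = c(mean / 3, 5 * mean / 3),
         high   = c(0, 2 * mean))
}
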