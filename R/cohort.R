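#' Draw the individual and cluster random effects
#'
#' Generates the latent structure of the cohort: one normal random effect per
#' subject (`eps`) and one per cluster (`u`, shared by all subjects of the
#' cluster).  Both act additively on the log hazards of the event and
#' mortality times, so they induce within-cluster correlation and
#' informative censoring by death.
#'
#' @param params A [cohort_params()] object.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return A data frame with `K * J` rows and columns `cluster`, `eps`, `u`.
#' @examples
#' head(draw_random_effects(cohort_params(J = 4, K = 3), seed = 1))
#' @export
draw_random_effects <- function(params, seed = NULL) {
  stopifnot(inherits(params, "cmrct_params"))
  if (!is.null(seed)) set.seed(check_seed(seed))
  N <- params$K * params$J
  cluster <- rep.int(seq_len(params$K), rep.int(params$J, params$K))
  eps <- stats::rnorm(N, 0, sqrt(params$sigma2_eps))
  u_k <- stats::rnorm(params$K, 0, sqrt(params$sigma2_u))
  data.frame(cluster = cluster, eps = eps, u = u_k[cluster])
}

#' Counterfactual 10-year event risk
#'
#' Probability that a subject with log-hazard offset `eps_plus_u` has a CVD
#' event within 10 years if untreated.  With baseline hazard
#' `h(t) = gamma_c * t^(gamma_c - 1) / lambda_c^gamma_c` multiplied by
#' `exp(eps_plus_u)`, the Weibull survivor function gives the closed form
#' `r = 1 - exp(-(10 / lambda_c)^gamma_c * exp(eps_plus_u))`.
#'
#' @param eps_plus_u Sum of the subject's random effects (vectorised).
#' @param gamma_c,lambda_c Weibull shape and scale of the event time.
#' @return Risk values strictly inside `(0, 1)`, increasing in
#'   `eps_plus_u`.
#' @examples
#' ten_year_risk(0, 1.2, 36)  # about 0.1935
#' @export
ten_year_risk <- function(eps_plus_u, gamma_c, lambda_c) {
  stopifnot(is.numeric(gamma_c), gamma_c > 0,
            is.numeric(lambda_c), lambda_c > 0)
  if (any(!is.finite(eps_plus_u)))
    stop("`eps_plus_u` contains non-finite values", call. = FALSE)
  1 - exp(-(10 / lambda_c)^gamma_c * exp(eps_plus_u))
}

#' Assign refusal probabilities correlated with risk
#'
#' Ranks the whole cohort by 10-year risk and spreads individual refusal
#' probabilities linearly between the tier's lower and upper limits along
#' that ranking: with a positive sign the lowest-risk subject receives the
#' lower limit and the highest-risk subject the upper limit; a negative sign
#' reverses the traversal.  Patient and clinician probabilities are assigned
#' on the same risk ordering, each with its own tier and sign.  Because every
#' tier is symmetric about the mean, the cohort mean equals the specified
#' mean exactly.  Rank ties (possible only under degenerate variances) are
#' broken by a uniform jitter drawn from the current RNG stream, so the
#' assignment is deterministic given the seed.
#'
#' @param cohort A cohort data frame containing `risk10` (see
#'   [simulate_cohort()]).
#' @param spec A [refusal_spec()] object.
#' @param seed Optional integer seed for the tie-breaking jitter.
#' @return `cohort` with columns `p_refuse` and `q_refuse` filled.
#' @export
assign_refusal <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(spec, "cmrct_refusal"), !is.null(cohort$risk10))
  if (!is.null(seed)) set.seed(check_seed(seed))
  N <- nrow(cohort)
  if (N < 2 && (spec$tier_p != "zero" || spec$tier_q != "zero"))
    stop("need at least 2 subjects for a non-zero correlation tier",
         call. = FALSE)
  ord <- order(cohort$risk10, stats::runif(N))  # ascending risk, jittered ties
  cohort$p_refuse <- refusal_grid(N, spec$p, spec$tier_p, spec$sign_p, ord)
  cohort$q_refuse <- refusal_grid(N, spec$q, spec$tier_q, spec$sign_q, ord)
  cohort
}

# Linear LL -> UL grid over the risk ranking `ord` (ascending risk).
refusal_grid <- function(N, mean, tier, sign, ord) {
  lim <- refusal_limits(mean, tier)
  if (lim[1] < -1e-12 || lim[2] > 1 + 1e-12)
    stop("refusal limits outside [0, 1]", call. = FALSE)
  if (tier == "zero" || mean == 0 || N == 1L) {
    g <- rep.int(mean, N)
  } else {
    g <- lim[1] + (seq_len(N) - 1) / (N - 1) * (lim[2] - lim[1])
    if (sign == "negative") g <- rev(g)
  }
  out <- numeric(N)
  out[ord] <- g
  out
}

#' Realised correlation between refusal probability and risk
#'
#' Diagnostic Pearson correlation between the assigned patient refusal
#' probabilities and the 10-year risks.  The generator controls this
#' correlation only through the tier width; this reports what was realised.
#' A constant refusal vector (zero tier, or mean 0) has no defined
#' correlation and is reported as 0 by convention.
#'
#' @param cohort Cohort data frame with `risk10` and `p_refuse` filled.
#' @param which Column to correlate with risk, `"p_refuse"` or `"q_refuse"`.
#' @return A correlation in `[-1, 1]`.
#' @export
refusal_risk_correlation <- function(cohort, which = "p_refuse") {
  which <- match.arg(which, c("p_refuse", "q_refuse"))
  x <- cohort[[which]]
  stopifnot(!is.null(x), !is.null(cohort$risk10))
  if (stats::sd(x) == 0 || stats::sd(cohort$risk10) == 0) return(0)
  stats::cor(x, cohort$risk10)
}

#' Generate a complete cohort
#'
#' Draws the random effects, computes each subject's counterfactual 10-year
#' risk, and assigns risk-correlated refusal probabilities.
#'
#' @param params A [cohort_params()] object.
#' @param spec A [refusal_spec()] object.
#' @param seed Optional integer seed making the cohort reproducible.
#' @return A data frame of class `cmrct_cohort` with columns `cluster`,
#'   `eps`, `u`, `risk10`, `p_refuse`, `q_refuse`.
#' @examples
#' cohort <- simulate_cohort(cohort_params(J = 10, K = 4),
#'                           refusal_spec(p = 0.2, tier_p = "high"),
#'                           seed = 7)
#' summary(cohort$risk10)
#' @export
simulate_cohort <- function(params, spec = refusal_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(check_seed(seed))
  cohort <- draw_random_effects(params)
  cohort$risk10 <- ten_year_risk(cohort$eps + cohort$u,
                                 params$gamma_c, params$lambda_c)
  cohort <- assign_refusal(cohort, spec)
  class(cohort) <- c("cmrct_cohort", "data.frame")
  attr(cohort, "params") <- params
  attr(cohort, "refusal") <- spec
  cohort
}

#' Write / read a cohort table
#'
#' Plain tab-separated export of the cohort frame for fixtures and external
#' checks.
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

# Validate a user-supplied seed: single non-negative integer below 2^31.
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed < 0 || seed != trunc(seed) || seed >= 2^31)
    stop("`seed` must be a single non-negative integer below 2^31",
         call. = FALSE)
  as.integer(seed)
}
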