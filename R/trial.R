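#' Randomise clusters to control or intervention on a 4:1 basis
#'
#' Allocates `round(K / 5)` clusters (at least one) to the intervention,
#' chosen uniformly at random without replacement; the remainder are
#' controls.
#'
#' @param K Number of clusters (`K >= 2`; `K >= 5` recommended so the 4:1
#'   ratio is meaningful).
#' @param seed Optional integer seed.
#' @return Integer vector of length `K` with `Z_k` in `{0, 1}`.
#' @examples
#' table(randomize_clusters(25, seed = 1))
#' @export
randomize_clusters <- function(K, seed = NULL) {
  K <- as.integer(K)
  if (!is.finite(K) || K < 2L) stop("`K` must be an integer >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(check_seed(seed))
  n_int <- max(1L, as.integer(round(K / 5)))
  z <- integer(K)
  z[sample.int(K, n_int)] <- 1L
  z
}

#' Treatment received under patient and clinician refusal
#'
#' Control subjects (`z = 0`) never receive the intervention.  An
#' intervention-arm subject receives it only if neither the patient nor the
#' clinician refuses: `x = min(Bernoulli(1 - p_ik), Bernoulli(1 - q_ik))`,
#' two independent draws, so acceptance has probability
#' `(1 - p_ik) * (1 - q_ik)`.
#'
#' @param z Allocation indicator per subject (0/1, vectorised).
#' @param p_ik,q_ik Patient and clinician refusal probabilities per subject.
#' @param seed Optional integer seed.
#' @return Integer vector `x` with `x <= z` elementwise.
#' @export
treatment_received <- function(z, p_ik, q_ik = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(check_seed(seed))
  n <- length(z)
  stopifnot(all(z %in% c(0, 1)),
            all(p_ik >= 0 & p_ik <= 1), all(q_ik >= 0 & q_ik <= 1))
  p_ik <- rep_len(p_ik, n)
  q_ik <- rep_len(q_ik, n)
  accept <- (stats::runif(n) < 1 - p_ik) & (stats::runif(n) < 1 - q_ik)
  as.integer(z == 1 & accept)
}

#' Sample a survival time from a proportional-hazards Weibull
#'
#' Draws from the distribution with hazard
#' `h(t) = shape * t^(shape - 1) / scale^shape * exp(linear_predictor)`,
#' i.e. a Weibull with survivor function `S(t) = exp(-(t / lambda*)^shape)`
#' where `lambda* = scale * exp(-linear_predictor / shape)`.  Sampling is by
#' inversion — one uniform draw per time — so larger linear predictors map
#' the same uniform to strictly smaller times.
#'
#' @param shape,scale Weibull shape and scale (both positive).
#' @param linear_predictor Log-hazard offset (vectorised; its length sets the
#'   number of draws unless `n` is given).
#' @param n Number of draws (defaults to `length(linear_predictor)`).
#' @param seed Optional integer seed.
#' @return Vector of positive times (years).
#' @examples
#' median(sample_event_time(1.2, 36, 0, n = 1e4, seed = 1))
#' @export
sample_event_time <- function(shape, scale, linear_predictor = 0,
                              n = length(linear_predictor), seed = NULL) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(scale) || scale <= 0)
    stop("`shape` and `scale` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(check_seed(seed))
  lp <- rep_len(linear_predictor, n)
  lambda_star <- scale * exp(-lp / shape)
  lambda_star * (-log(stats::runif(n)))^(1 / shape)
}

#' Apply death and administrative censoring
#'
#' Observed follow-up is `y = min(t_c, t_m, T_max)`; the censoring indicator
#' is `c = 1` exactly when the CVD event is pre-empted by death or by the end
#' of follow-up, `t_c >= min(t_m, T_max)`.
#'
#' @param t_c Latent CVD event times.
#' @param t_m Latent mortality times.
#' @param T_max Follow-up horizon (years).
#' @return A list with components `y` (observed time) and `c` (censoring
#'   indicator, 1 = censored).
#' @examples
#' apply_censoring(4, 5, 3)  # administratively censored at 3 years
#' @export
apply_censoring <- function(t_c, t_m, T_max) {
  stopifnot(all(t_c > 0), all(t_m > 0), T_max > 0)
  list(y = pmin(t_c, t_m, T_max),
       c = as.integer(t_c >= pmin(t_m, T_max)))
}

#' Simulate one cluster cmRCT from a cohort
#'
#' Composes the trial steps: 4:1 cluster randomisation, treatment uptake
#' under patient/clinician refusal, Weibull event and mortality times with
#' the random effects (and, for the event time only, the intervention effect
#' `beta * x`) on the log hazard, then censoring by death and at `T_max`.
#' The latent times are retained for diagnostics but are not used by any
#' estimator.
#'
#' @param cohort A [simulate_cohort()] data frame.
#' @param params The [cohort_params()] used to generate the cohort.
#' @param seed Optional integer seed making the trial reproducible.
#' @return A data frame of class `cmrct_trial` with columns `cluster`, `z`,
#'   `x`, `y`, `c` and latent `t_c`, `t_m`.
#' @examples
#' params <- cohort_params(J = 50, K = 10)
#' trial <- simulate_trial(simulate_cohort(params, seed = 1), params, seed = 2)
#' with(trial, table(z, x))
#' @export
simulate_trial <- function(cohort, params, seed = NULL) {
  stopifnot(inherits(params, "cmrct_params"),
            !is.null(cohort$p_refuse), !is.null(cohort$q_refuse))
  if (!is.null(seed)) set.seed(check_seed(seed))
  K <- max(cohort$cluster)
  z_k <- randomize_clusters(K)
  z <- z_k[cohort$cluster]
  x <- treatment_received(z, cohort$p_refuse, cohort$q_refuse)
  lp_c <- params$beta * x + cohort$eps + cohort$u
  lp_m <- cohort$eps + cohort$u
  t_c <- sample_event_time(params$gamma_c, params$lambda_c, lp_c)
  t_m <- sample_event_time(params$gamma_m, params$lambda_m, lp_m)
  cens <- apply_censoring(t_c, t_m, params$T_max)
  out <- data.frame(cluster = cohort$cluster, z = z, x = x,
                    y = cens$y, c = cens$c, t_c = t_c, t_m = t_m)
  class(out) <- c("cmrct_trial", "data.frame")
  attr(out, "params") <- params
  out
}

#' Write / read a trial survival table
#'
#' Tab-separated export of the observed trial data `{cluster, z, x, y, c}`;
#' set `latent = TRUE` to also keep the latent event and mortality times.
#'
#' @param trial A trial data frame.
#' @param path File path.
#' @param latent Keep the latent `t_c`, `t_m` columns?
#' @return `write_trial()` returns `path` invisibly; `read_trial()` the data
#'   frame.
#' @export
write_trial <- function(trial, path, latent = FALSE) {
  cols <- c("cluster", "z", "x", "y", "c", if (latent) c("t_c", "t_m"))
  utils::write.table(as.data.frame(trial)[cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("cmrct_trial", "data.frame")
  out
}
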