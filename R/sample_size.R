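#' Simulation-based sample-size determination
#'
#' Finds the smallest number of clusters `K` (so the smallest cohort size
#' `N = K * J`, a multiple of the cluster size) whose simulated ITT power
#' reaches the target.  For each candidate `K`, `reps` trials are simulated
#' with non-informative refusal — every subject refuses with the same
#' probability `assumed_refusal`, independent of risk — analysed by ITT with
#' the chosen Cox model, and the power is the fraction of Wald p-values
#' below `alpha`.  Recruitment method 1 is the call with
#' `assumed_refusal = 0` (refusal ignored in the design); recruitment
#' method 2 supplies the anticipated refusal rate so the design is inflated
#' to preserve power.
#'
#' The search doubles `K` until the target is bracketed and then bisects.
#' All candidates reuse one fixed set of replicate seeds (common random
#' numbers), which makes the estimated power curve monotone in practice and
#' stabilises the minimality of the returned `K`.
#'
#' @param params A [cohort_params()] object; its `K` is ignored.
#' @param assumed_refusal Overall refusal probability assumed in the design,
#'   in `[0, 1)`.
#' @param alpha Type-I error of the Wald test.
#' @param target_power Required power.
#' @param reps Simulated trials per candidate `K` (200 or more
#'   recommended).
#' @param model Cox clustering treatment used for the ITT analysis.
#' @param K_min,K_max Search range for the number of clusters.
#' @param base_seed Integer seed for the common replicate seed stream.
#' @param verbose Print one line per candidate?
#' @return An object of class `cmrct_samplesize`: `K_star`, `N_star`
#'   (`= K_star * J`), `achieved_power`, `reps_used`, `method` (1 or 2),
#'   `assumed_refusal`, and the evaluated `power_curve`.
#' @examples
#' params <- cohort_params(J = 60, K = 10, lambda_c = 8, beta = -0.7)
#' find_sample_size(params, reps = 40, K_min = 5, K_max = 80, base_seed = 1)
#' @export
find_sample_size <- function(params, assumed_refusal = 0, alpha = 0.05,
                             target_power = 0.8, reps = 200,
                             model = "lognormal", K_min = 5L, K_max = 500L,
                             base_seed = 1, verbose = FALSE) {
  stopifnot(assumed_refusal >= 0, assumed_refusal < 1, reps >= 2)
  spec <- refusal_spec(p = assumed_refusal, tier_p = "zero")
  set.seed(check_seed(base_seed))
  rep_seeds <- sample.int(2147483647L, reps)
  cache <- new.env(parent = emptyenv())
  power_at <- function(K) {
    key <- as.character(K)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pars <- params
    pars$K <- as.integer(K)
    rej <- 0L; used <- 0L
    for (j in seq_len(reps)) {
      set.seed(rep_seeds[j])
      trial <- simulate_trial(simulate_cohort(pars, spec), pars)
      est <- estimate_itt(trial, model = model)
      if (isTRUE(est$converged)) {
        used <- used + 1L
        if (est$pvalue < alpha) rej <- rej + 1L
      }
    }
    pw <- if (used > 0) rej / used else 0
    cache[[key]] <- pw
    if (verbose) cat(sprintf("  K = %d: power %.3f (%d usable reps)\n",
                             K, pw, used))
    pw
  }
  # coarse doubling to bracket the target
  K <- as.integer(K_min)
  while (power_at(K) < target_power) {
    if (K >= K_max) {
      curve <- power_curve(cache)
      stop("target power not reached by K_max = ", K_max,
           "; evaluated curve:\n",
           paste(utils::capture.output(print(curve)), collapse = "\n"),
           call. = FALSE)
    }
    K <- min(as.integer(K_max), 2L * K)
  }
  lo <- max(as.integer(K_min) - 1L, as.integer(K / 2))  # power(lo) < target (or floor)
  hi <- K                                               # power(hi) >= target
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (power_at(mid) >= target_power) hi <- mid else lo <- mid
  }
  structure(list(K_star = hi, N_star = hi * params$J,
                 achieved_power = power_at(hi), reps_used = reps,
                 method = if (assumed_refusal > 0) 2L else 1L,
                 assumed_refusal = assumed_refusal,
                 alpha = alpha, target_power = target_power,
                 power_curve = power_curve(cache),
                 params = params, model = model, base_seed = base_seed),
            class = "cmrct_samplesize")
}

power_curve <- function(cache) {
  Ks <- sort(as.integer(ls(cache)))
  data.frame(K = Ks, power = vapply(as.character(Ks),
                                    function(k) cache[[k]], numeric(1)))
}

#' @export
print.cmrct_samplesize <- function(x, ...) {
  cat(sprintf("Simulation-based sample size (recruitment method %d)\n", x$method))
  cat(sprintf("  assumed refusal: %.2g, target power %.2g at alpha %.2g\n",
              x$assumed_refusal, x$target_power, x$alpha))
  cat(sprintf("  K* = %d clusters, N* = %d subjects (J = %d)\n",
              x$K_star, x$N_star, x$params$J))
  cat(sprintf("  achieved power: %.3f (%d reps per candidate)\n",
              x$achieved_power, x$reps_used))
  invisible(x)
}

#' Revise a sample size with an observed refusal rate
#'
#' Re-runs the simulation-based search with the refusal rate observed during
#' the trial in place of the one assumed at the design stage, keeping every
#' other design parameter (effect size, clustering, alpha, power target and
#' seed stream) fixed.
#'
#' @param current A [find_sample_size()] result.
#' @param observed_refusal Refusal rate observed so far, in `[0, 1)`.
#' @param reps Optionally override the replicate count.
#' @return A new `cmrct_samplesize` object with the change in clusters in
#'   `$delta_K`.
#' @export
update_sample_size <- function(current, observed_refusal, reps = NULL) {
  stopifnot(inherits(current, "cmrct_samplesize"),
            observed_refusal >= 0, observed_refusal < 1)
  revised <- find_sample_size(current$params,
                              assumed_refusal = observed_refusal,
                              alpha = current$alpha,
                              target_power = current$target_power,
                              reps = if (is.null(reps)) current$reps_used else reps,
                              model = current$model,
                              base_seed = current$base_seed)
  revised$delta_K <- revised$K_star - current$K_star
  revised
}
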