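# Small, event-rich parameter sets for fast fitting in unit tests.
# lambda_c = 8 raises the 3-year event fraction to roughly 30%, so Cox fits
# on a few hundred subjects are informative and quick.

fast_params <- function(...) {
  args <- utils::modifyList(list(J = 80L, K = 12L, lambda_c = 8), list(...))
  do.call(cohort_params, args)
}

fast_trial <- function(seed, spec = refusal_spec(), params = fast_params()) {
  set.seed(seed)
  simulate_trial(simulate_cohort(params, spec), params)
}

# Hand-enumerated Cox partial likelihood (Breslow form; exact with distinct
# event times).  Used as an independent oracle for the model fitter.
neg_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  -ll
}
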