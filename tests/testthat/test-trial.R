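test_that("cluster randomisation keeps the 4:1 ratio", {
  expect_equal(sum(randomize_clusters(5, seed = 1)), 1)
  expect_equal(sum(randomize_clusters(10, seed = 2)), 2)
  expect_equal(sum(randomize_clusters(7, seed = 3)), 1)   # round(7/5)
  expect_equal(sum(randomize_clusters(25, seed = 4)), 5)
  expect_equal(sum(randomize_clusters(2, seed = 5)), 1)   # floor of one
  expect_error(randomize_clusters(1), ">= 2")
  # allocation is uniform over clusters: every cluster is picked sometimes
  picks <- replicate(200, which(randomize_clusters(5) == 1))
  expect_setequal(unique(picks), 1:5)
})

test_that("treatment received obeys allocation and refusal probabilities", {
  expect_true(all(treatment_received(rep(0, 100), 0, 0) == 0))
  expect_true(all(treatment_received(rep(1, 100), 0, 0) == 1))
  expect_true(all(treatment_received(rep(1, 100), 1, 0) == 0))
  expect_true(all(treatment_received(rep(1, 100), 0, 1) == 0))
  # two independent refusal draws: acceptance = (1-p)(1-q) = 0.64
  set.seed(8)
  x <- treatment_received(rep(1, 2e5), 0.2, 0.2)
  expect_equal(mean(x), 0.64, tolerance = 0.005)
})

test_that("event-time sampler matches the Weibull law it claims", {
  # closed-form median at zero linear predictor
  med <- median(sample_event_time(1.2, 36, 0, n = 2e5, seed = 1))
  expect_equal(med, 36 * log(2)^(1 / 1.2), tolerance = 0.25)
  # KS agreement with the analytic survivor function at a non-zero offset
  lp <- 0.5
  tt <- sample_event_time(1.2, 36, lp, n = 1e5, seed = 2)
  ks <- suppressWarnings(
    ks.test(tt, pweibull, shape = 1.2, scale = 36 * exp(-lp / 1.2)))
  expect_gt(ks$p.value, 0.01)
  # empirical 10-year probability matches ten_year_risk
  expect_equal(mean(sample_event_time(1.2, 36, 0, n = 2e5, seed = 3) <= 10),
               ten_year_risk(0, 1.2, 36), tolerance = 0.005)
  # proportional hazards: larger linear predictor, same uniforms,
  # strictly smaller times
  t0 <- sample_event_time(1.2, 36, 0, n = 1000, seed = 4)
  t1 <- sample_event_time(1.2, 36, 1, n = 1000, seed = 4)
  expect_true(all(t1 < t0))
  expect_error(sample_event_time(-1, 36, 0, n = 1), "positive")
})

test_that("censoring indicator and observed time follow their definitions", {
  expect_equal(apply_censoring(1, 5, 3), list(y = 1, c = 0L))    # event
  expect_equal(apply_censoring(4, 5, 3), list(y = 3, c = 1L))    # administrative
  expect_equal(apply_censoring(2.5, 2, 3), list(y = 2, c = 1L))  # death first
  expect_equal(apply_censoring(3, 5, 3), list(y = 3, c = 1L))    # boundary
})

test_that("simulated trials satisfy their structural invariants", {
  params <- cohort_params(J = 100, K = 10)
  spec <- refusal_spec(p = 0.3, tier_p = "high", sign_p = "negative")
  set.seed(21)
  trial <- simulate_trial(simulate_cohort(params, spec), params)
  expect_true(all(tapply(trial$z, trial$cluster, function(v)
    length(unique(v))) == 1))
  expect_true(all(trial$x <= trial$z))
  expect_equal(trial$y, pmin(trial$t_c, trial$t_m, params$T_max))
  expect_equal(trial$c,
               as.integer(trial$t_c >= pmin(trial$t_m, params$T_max)))
  expect_true(all(trial$y > 0 & trial$y <= params$T_max))
  # determinism
  set.seed(33)
  co <- simulate_cohort(params, spec)
  expect_equal(simulate_trial(co, params, seed = 5),
               simulate_trial(co, params, seed = 5))
  # export round-trip of the observed table
  f <- tempfile(fileext = ".tsv")
  write_trial(trial, f)
  expect_equal(read_trial(f)$y, trial$y, tolerance = 1e-12)
  unlink(f)
})

test_that("shared random effects induce the latent-time dependence", {
  params <- cohort_params(J = 100, K = 1000)
  set.seed(6)
  co <- simulate_cohort(params)
  trial <- simulate_trial(co, params)
  # positive dependence through the shared frailty; the closed form for
  # this Weibull pair at total variance 0.8 gives 0.378
  expect_equal(cor(trial$t_c, trial$t_m), 0.378, tolerance = 0.03)
  # independence when both variances vanish
  p0 <- cohort_params(J = 100, K = 200, sigma2_eps = 0, sigma2_u = 0)
  set.seed(7)
  tr0 <- simulate_trial(simulate_cohort(p0), p0)
  expect_lt(abs(cor(tr0$t_c, tr0$t_m)), 0.02)
})

test_that("null effect with full compliance leaves arms exchangeable", {
  # no cluster effect so the iid KS null applies across arms
  params <- cohort_params(J = 200, K = 20, beta = 0, sigma2_u = 0)
  set.seed(11)
  trial <- simulate_trial(simulate_cohort(params), params)
  expect_true(all(trial$x == trial$z))
  ks <- suppressWarnings(ks.test(trial$t_c[trial$z == 1],
                                 trial$t_c[trial$z == 0]))
  expect_gt(ks$p.value, 0.01)
})
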