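test_that("random effects have the requested structure and are reproducible", {
  params <- cohort_params(J = 50, K = 8)
  re1 <- draw_random_effects(params, seed = 42)
  re2 <- draw_random_effects(params, seed = 42)
  expect_identical(re1, re2)
  expect_equal(nrow(re1), 400)
  # u is shared within, and varies between, clusters
  expect_true(all(tapply(re1$u, re1$cluster, function(v) length(unique(v))) == 1))
  expect_gt(length(unique(re1$u)), 1)

  # degenerate variances give exact zeros
  re0 <- draw_random_effects(cohort_params(J = 10, K = 4, sigma2_eps = 0,
                                           sigma2_u = 0), seed = 1)
  expect_true(all(re0$eps == 0) && all(re0$u == 0))

  # sample variances match sigma2 at large N (MC tolerance)
  big <- draw_random_effects(cohort_params(J = 500, K = 200), seed = 7)
  expect_equal(var(big$eps), 0.6, tolerance = 0.02)
  expect_equal(var(big$u[!duplicated(big$cluster)]), 0.2, tolerance = 0.15)
})

test_that("parameter validation rejects impossible inputs", {
  expect_error(cohort_params(sigma2_eps = -1), "non-negative")
  expect_error(cohort_params(lambda_c = 0), "positive")
  expect_error(cohort_params(J = 1))
  expect_error(refusal_spec(p = 0.6, tier_p = "high"), "above 1")
  expect_error(refusal_spec(p = 1.2))
})

test_that("ten-year risk matches the Weibull survivor closed form", {
  # closed form vs numerical integration of the hazard over [0, 10]
  risk_by_integration <- function(w, gamma_c, lambda_c) {
    H <- integrate(function(t) gamma_c * t^(gamma_c - 1) / lambda_c^gamma_c *
                     exp(w), 0, 10, rel.tol = 1e-10)$value
    1 - exp(-H)
  }
  for (w in c(-2, -0.5, 0, 0.7, 1.5))
    expect_equal(ten_year_risk(w, 1.2, 36), risk_by_integration(w, 1.2, 36),
                 tolerance = 1e-6)
  expect_equal(ten_year_risk(0, 1.2, 36), 1 - exp(-(10 / 36)^1.2),
               tolerance = 1e-12)

  # strictly increasing, bounded in (0, 1), degenerate limits
  # (beyond w ~ 5 the risk saturates to 1 in double precision)
  w <- seq(-8, 4, length.out = 200)
  r <- ten_year_risk(w, 1.2, 36)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  expect_lt(ten_year_risk(-30, 1.2, 36), 1e-10)
  expect_equal(ten_year_risk(30, 1.2, 36), 1)
  expect_error(ten_year_risk(NaN, 1.2, 36), "non-finite")
})

test_that("refusal assignment is rank-linear with exact mean", {
  # linear interpolation on a 3-subject cohort, high tier
  co <- data.frame(cluster = 1:3, risk10 = c(0.3, 0.1, 0.2))
  spec <- refusal_spec(p = 0.2, tier_p = "high", sign_p = "positive")
  out <- assign_refusal(co, spec, seed = 1)
  expect_equal(out$p_refuse[order(out$risk10)], c(0, 0.2, 0.4))
  # negative sign reverses the traversal
  spec_n <- refusal_spec(p = 0.2, tier_p = "high", sign_p = "negative")
  out_n <- assign_refusal(co, spec_n, seed = 1)
  expect_equal(out_n$p_refuse[order(out_n$risk10)], c(0.4, 0.2, 0))

  # the mean is exact for every tier/sign/N
  for (tier in c("zero", "low", "medium", "high"))
    for (sgn in c("positive", "negative"))
      for (N in c(2, 7, 100)) {
        co <- data.frame(risk10 = runif(N))
        sp <- refusal_spec(p = 0.27, q = 0.1, tier_p = tier, sign_p = sgn,
                           tier_q = tier, sign_q = sgn)
        out <- assign_refusal(co, sp, seed = 3)
        expect_equal(mean(out$p_refuse), 0.27, tolerance = 1e-9)
        expect_equal(mean(out$q_refuse), 0.1, tolerance = 1e-9)
        expect_true(all(out$p_refuse >= 0 & out$p_refuse <= 1))
      }

  # degenerate mean: p = 0 gives all-zero refusal whatever the tier
  co <- data.frame(risk10 = runif(10))
  out <- assign_refusal(co, refusal_spec(p = 0, tier_p = "high"), seed = 1)
  expect_true(all(out$p_refuse == 0))

  # permutation equivariance: shuffling rows keeps the (risk, p) pairing
  co <- data.frame(risk10 = runif(50))
  sp <- refusal_spec(p = 0.2, tier_p = "medium", sign_p = "positive")
  a <- assign_refusal(co, sp, seed = 9)
  perm <- sample(50)
  b <- assign_refusal(co[perm, , drop = FALSE], sp, seed = 9)
  expect_equal(a[perm, c("risk10", "p_refuse")], b[, c("risk10", "p_refuse")],
               ignore_attr = TRUE)

  expect_error(assign_refusal(data.frame(risk10 = 0.5),
                              refusal_spec(p = 0.2, tier_p = "high")),
               "at least 2")
})

test_that("realised refusal-risk correlation behaves with tier and sign", {
  set.seed(5)
  co <- data.frame(risk10 = runif(500))
  zero <- assign_refusal(co, refusal_spec(p = 0.2, tier_p = "zero"))
  expect_identical(refusal_risk_correlation(zero), 0)
  hi_pos <- assign_refusal(co, refusal_spec(p = 0.2, tier_p = "high",
                                            sign_p = "positive"))
  hi_neg <- assign_refusal(co, refusal_spec(p = 0.2, tier_p = "high",
                                            sign_p = "negative"))
  lo_pos <- assign_refusal(co, refusal_spec(p = 0.2, tier_p = "low",
                                            sign_p = "positive"))
  expect_gt(refusal_risk_correlation(hi_pos), 0)
  expect_lt(refusal_risk_correlation(hi_neg), 0)
  expect_gte(abs(refusal_risk_correlation(hi_pos)),
             abs(refusal_risk_correlation(lo_pos)))
})

test_that("cohort generation is reproducible and exports round-trip", {
  params <- cohort_params(J = 20, K = 5)
  spec <- refusal_spec(p = 0.3, tier_p = "low")
  c1 <- simulate_cohort(params, spec, seed = 13)
  c2 <- simulate_cohort(params, spec, seed = 13)
  expect_equal(c1, c2)
  expect_true(all(c1$risk10 > 0 & c1$risk10 < 1))
  f <- tempfile(fileext = ".tsv")
  write_cohort(c1, f)
  back <- read_cohort(f)
  expect_equal(back$risk10, c1$risk10, tolerance = 1e-12)
  unlink(f)
})
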