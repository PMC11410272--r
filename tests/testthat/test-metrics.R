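# Frozen micro-oracles (computed from independent likelihood code before the
# estimators were written):
#   logistic 6-row example: slope 2.6702240524 (optim on the Bernoulli
#     log-likelihood, reltol 1e-14, confirmed by profile grid search)
#   Cox 4-subject example: log-HR 0.9406136133 (optimize on the explicit
#     Breslow partial likelihood, tol 1e-12)

test_that("standardisation is the forced affine map and is idempotent", {
  expect_equal(standardize_prs(c(0, 2)), c(-1, 1))
  x <- rnorm(50)
  z <- standardize_prs(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(standardize_prs(z), z, tolerance = 1e-12)
  expect_error(standardize_prs(rep(3, 10)), "degenerate")
})

test_that("an ancestry-reference map leaves other groups with non-unit SD", {
  withr::with_seed(4, {
    ref <- rnorm(2000, 0, 1)
    other <- rnorm(2000, 0.4, 1.6)
  })
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  x <- c(ref, other)
  z <- standardize_prs(x, reference = c(rep(TRUE, 2000), rep(FALSE, 2000)))
  expect_equal(psd(z[1:2000]), 1, tolerance = 1e-12)
  # direct recomputation: the other group's SD is its raw SD over the reference SD
  expect_equal(psd(z[2001:4000]), psd(other) / psd(ref), tolerance = 1e-12)
  expect_gt(abs(psd(z[2001:4000]) - 1), 0.1)
})

test_that("logistic per-SD estimate matches the frozen grid-search MLE to 1e-6", {
  fr <- make_frame(c(-1.2, -0.5, 0, 0.4, 0.9, 1.6), case = c(0, 0, 1, 0, 1, 1))
  est <- or_per_sd(fr, covariates = character(), standardize = FALSE)
  expect_equal(est$log_estimate, 2.6702240524, tolerance = 1e-6)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
})

test_that("logistic regression flags complete separation and null effects", {
  withr::with_seed(7, {
    prs <- rnorm(400)
    fr_sep <- make_frame(prs, case = as.integer(prs > 0))
    expect_error(or_per_sd(fr_sep, covariates = character()), "separation")
    fr_null <- make_frame(prs, case = sample(rep(0:1, 200)))
  })
  est <- or_per_sd(fr_null, covariates = character())
  expect_lt(abs(est$log_estimate), 0.3)
  expect_true(est$ci_low < 1 && est$ci_high > 1)
})

test_that("Cox per-SD estimate matches the enumerated partial-likelihood oracle", {
  fr <- make_frame(c(1, 0, 1, 0),
    case = c(1, 1, 1, 1), event_age = c(2, 3, 5, 7),
    censor_age = c(2, 3, 5, 7)
  )
  est <- hr_per_sd(fr, covariates = character(), standardize = FALSE, mode = "lifetime")
  expect_equal(est$log_estimate, 0.9406136133, tolerance = 1e-6)
  # degenerate score
  fr2 <- make_frame(rep(1, 4), case = c(1, 1, 0, 0), event_age = c(2, 3, NA, NA))
  expect_error(hr_per_sd(fr2, covariates = character()), "degenerate|singular")
  # all censored
  fr3 <- make_frame(c(1, 2, 3), case = c(0, 0, 0))
  expect_error(hr_per_sd(fr3, covariates = character()), "no events")
})

test_that("Cox estimator recovers a known hazard effect inside its CI", {
  cfg <- sim_config(
    n_per_ancestry = c(EUR = 30000),
    diseases = list(list(
      trait_code = "D", score = "PRS_CAD", log_hr_per_sd = 0.3,
      sex_log_hr = 0, age_slope = 0,
      baseline = list(breaks = c(0, 40, 60, 120), rates = c(5e-4, 5e-3, 1e-2))
    )),
    mortality = list(
      baseline = list(breaks = c(0, 110), rates = 1e-3),
      log_hr_per_sd = c(PRS_CAD = 0)
    )
  )
  sim <- simulate_cohort(cfg, seed = 33)
  fr <- align(sim$cohort, sim$scores, sim$phenotypes$D)
  est <- hr_per_sd(fr, covariates = character())
  expect_gt(0.3, log(est$ci_low))
  expect_lt(0.3, log(est$ci_high))
})

test_that("per-SD estimates are invariant to rescaling the raw score", {
  sim <- small_sim()
  fr <- align(eur_cohort(sim), sim$scores, sim$phenotypes$CAD)
  fr2 <- fr
  fr2$prs <- fr$prs * 7.3 + 2
  for (f in list(or_per_sd, function(...) hr_per_sd(...))) {
    expect_equal(f(fr)$log_estimate, f(fr2)$log_estimate, tolerance = 1e-8)
  }
})

test_that("quantitative effect: identity, null and generative recovery with incremental r2", {
  x <- withr::with_seed(5, rnorm(300))
  fr_id <- make_frame(x, value = x)
  est <- beta_per_sd(fr_id, covariates = character())
  expect_equal(est$estimate, 1, tolerance = 1e-9)
  expect_equal(est$r2, 1, tolerance = 1e-9)

  fr_null <- make_frame(x, value = withr::with_seed(6, rnorm(300)))
  est0 <- beta_per_sd(fr_null, covariates = character())
  expect_lt(abs(est0$estimate), 0.15)
  expect_lt(est0$r2, 0.02)

  withr::with_seed(8, {
    n <- 100000
    prs <- rnorm(n)
    y <- 0.3 * prs + rnorm(n, 0, 0.954)
  })
  fr <- make_frame(prs, value = y)
  est3 <- beta_per_sd(fr, covariates = character())
  expect_equal(est3$estimate, 0.3, tolerance = 0.02)
  expect_equal(est3$r2, 0.09, tolerance = 0.01)
  expect_error(beta_per_sd(make_frame(x, value = rep(2, 300))), "onstant")
})

test_that("AUC equals exhaustive pair counting and respects forced cases", {
  # cases {3, 2} vs controls {1, 2}: pairs 3>1, 3>2, 2>1 and one tie -> 3.5/4
  fr <- make_frame(c(3, 2, 1, 2), case = c(1, 1, 0, 0))
  expect_equal(auc_prs(fr)$estimate, 0.875)
  fr_perf <- make_frame(c(5, 4, 1, 2), case = c(1, 1, 0, 0))
  expect_equal(auc_prs(fr_perf)$estimate, 1)
  expect_error(auc_prs(make_frame(1:3, case = c(1, 1, 1))), "case and.*control")
})

test_that("AUC is invariant under strictly increasing transforms and matches pROC's DeLong CI", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    prs <- rnorm(500)
    case <- rbinom(500, 1, plogis(-1 + prs))
  })
  fr <- make_frame(prs, case = case)
  a1 <- auc_prs(fr)
  fr2 <- make_frame(exp(2 * prs) + 5, case = case)
  expect_equal(a1$estimate, auc_prs(fr2)$estimate, tolerance = 1e-12)
  ref <- pROC::ci.auc(pROC::roc(case, prs, quiet = TRUE, direction = "<"), method = "delong")
  expect_equal(a1$estimate, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(a1$ci_low, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(a1$ci_high, as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("effective sample size formulas: direct values, limits and the algebraic identity", {
  expect_equal(effective_sample_size_meta(1000, 0.5), 1000)
  expect_equal(effective_sample_size_meta(c(1000, 2000), c(0.1, 0.25)), 4 * (1000 * 0.09 + 2000 * 0.1875))
  expect_equal(effective_sample_size_meta(numeric(), numeric()), 0)
  expect_error(effective_sample_size_meta(100, 1), "strictly inside")

  expect_equal(effective_sample_size_cc(500, 500), 1000)
  expect_equal(effective_sample_size_cc(1000, 1000), 2000)
  expect_equal(effective_sample_size_cc(1e9, 106), 4 * 106, tolerance = 1e-3)
  expect_error(effective_sample_size_cc(0, 10), "positive")

  # single-study identity: 4/((1/n0)+(1/n1)) == 4*n*c*(1-c) with c = n1/n
  for (cnt in list(c(700, 300), c(120, 5), c(1, 1))) {
    n0 <- cnt[1]
    n1 <- cnt[2]
    expect_equal(
      effective_sample_size_cc(n0, n1),
      effective_sample_size_meta(n0 + n1, n1 / (n0 + n1)),
      tolerance = 1e-12
    )
  }
})
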