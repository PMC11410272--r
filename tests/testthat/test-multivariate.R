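test_that("correlation matrix: diagonal, negation, exact symmetry, null independence", {
  withr::with_seed(17, {
    a <- rnorm(10000)
    b <- rnorm(10000)
  })
  sc <- score_set(data.frame(
    individual_id = sprintf("I%05d", 1:10000),
    A = a, NEG_A = -a, B = b
  ))
  cm <- prs_correlation_matrix(sc)
  expect_equal(diag(unclass(cm)), c(A = 1, NEG_A = 1, B = 1))
  expect_equal(cm["A", "NEG_A"], -1)
  expect_lt(abs(cm["A", "B"]), 0.05)
  expect_identical(unclass(cm)[lower.tri(cm)], t(unclass(cm))[lower.tri(cm)])

  sc_bad <- score_set(data.frame(individual_id = c("a", "b", "c"), A = 1:3, B = rep(2, 3)))
  cm_bad <- prs_correlation_matrix(sc_bad)
  expect_true(all(is.na(cm_bad["B", "A"])))
  expect_error(cluster_order(cm_bad), "undefined")
})

test_that("cluster order merges the closest pair first and is permutation-invariant", {
  # hand linkage oracle: d(A,B) small, C far away -> A,B adjacent leaves
  M <- matrix(c(
    1, 0.99, 0.1,
    0.99, 1, 0.12,
    0.1, 0.12, 1
  ), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  class(M) <- c("prs_cormat", class(M))
  ord <- cluster_order(M)
  expect_true(abs(which(ord == "A") - which(ord == "B")) == 1)

  perm <- c("C", "A", "B")
  M2 <- M[perm, perm]
  class(M2) <- c("prs_cormat", class(M2))
  expect_identical(cluster_order(M2), ord)

  # identical rows merge at distance zero, hence adjacent
  sc <- score_set(data.frame(
    individual_id = sprintf("I%03d", 1:200),
    X1 = withr::with_seed(3, rnorm(200)), X3 = withr::with_seed(9, rnorm(200))
  ))
  sc$X2 <- sc$X1
  cm <- prs_correlation_matrix(sc)
  ord2 <- cluster_order(cm)
  expect_true(abs(which(ord2 == "X1") - which(ord2 == "X2")) == 1)
})

test_that("Harrell's C matches exhaustive pair enumeration and its invariances", {
  # 4 subjects, all events, one discordant pair of six
  expect_equal(harrells_c(c(4, 3, 1, 2), 1:4, rep(TRUE, 4))$c, 5 / 6)
  # perfect risk ranking
  expect_equal(harrells_c(4:1, 1:4, rep(TRUE, 4))$c, 1)
  # random predictions hover at 1/2
  withr::with_seed(23, {
    t <- rexp(2000)
    p <- rnorm(2000)
  })
  expect_lt(abs(harrells_c(p, t, rep(TRUE, 2000))$c - 0.5), 0.03)
  # invariant under strictly increasing transform of predictions
  expect_equal(
    harrells_c(exp(p), t, rep(TRUE, 2000))$c,
    harrells_c(p, t, rep(TRUE, 2000))$c
  )
  expect_error(harrells_c(1:3, 1:3, rep(FALSE, 3)), "no events")
})

test_that("Royston's R2_D: null is zero, bounded, monotone in predictor strength", {
  withr::with_seed(29, {
    n <- 3000
    x <- rnorm(n)
    t_strong <- rexp(n, exp(1.0 * x) * 0.1)
    t_weak <- rexp(n, exp(0.2 * x) * 0.1)
  })
  expect_equal(royston_r2(rep(0, n), t_strong, rep(TRUE, n)), 0)
  r_strong <- royston_r2(x, t_strong, rep(TRUE, n))
  r_weak <- royston_r2(x, t_weak, rep(TRUE, n))
  expect_gt(r_strong, r_weak)
  for (r in c(r_strong, r_weak)) expect_true(r >= 0 && r < 1)
})

test_that("stepwise selection: forced-empty, null candidates, true-signal recovery", {
  cfg <- sim_config(
    n_per_ancestry = c(EUR = 15000),
    score_names = c("PRS_TRUE", paste0("PRS_N", 1:5)),
    mortality = list(
      baseline = list(breaks = c(0, 40, 50, 60, 70, 80, 90, 110),
                      rates = c(5e-4, 1e-3, 3e-3, 8e-3, 2.5e-2, 8e-2, 0.25)),
      log_hr_per_sd = c(PRS_TRUE = 0.25, PRS_N1 = 0, PRS_N2 = 0, PRS_N3 = 0, PRS_N4 = 0, PRS_N5 = 0)
    )
  )
  sim <- simulate_cohort(cfg, seed = 303)
  m <- stepwise_mortality(sim$cohort, sim$scores, "own", c_diff_boot = 25, seed = 1)
  expect_identical(m$selected, "PRS_TRUE")
  expect_gt(m$c_full, m$c_reduced)
  expect_gt(m$royston_r2, 0)
  # entry_p = 0 can never admit a candidate
  m0 <- stepwise_mortality(sim$cohort, sim$scores, "own", entry_p = 0, c_diff_boot = 0)
  expect_length(m0$selected, 0)
  # all-null candidates stay out at a strict threshold
  m_null <- stepwise_mortality(sim$cohort, sim$scores, "own",
    candidates = paste0("PRS_N", 1:5), c_diff_boot = 0
  )
  expect_length(m_null$selected, 0)
})

test_that("own and parental mortality effects show the 2:1 attenuation at rho = 0.5", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 30000), followup_years = 25)
  sim <- simulate_cohort(cfg, seed = 404)
  m_own <- stepwise_mortality(sim$cohort, sim$scores, "own", c_diff_boot = 0)
  m_par <- stepwise_mortality(sim$cohort, sim$scores, "parental", c_diff_boot = 0)
  expect_identical(m_own$selected, "PRS_CAD")
  expect_identical(m_par$selected, "PRS_CAD")
  r <- parent_offspring_ratio(m_own, m_par, "PRS_CAD")
  expect_true(r$ci_low <= 2 && 2 <= r$ci_high)
  # trio-regression core: the parental slope is about half the own slope
  expect_equal(r$log_hr_parental / r$log_hr_own, 0.5, tolerance = 0.2)
  # arithmetic contract of the ratio itself
  fake <- function(b, se) {
    list(target = "x", coefficients = data.frame(score = "S", log_hr = b, se = se))
  }
  expect_equal(parent_offspring_ratio(fake(0.10, 0.001), fake(0.05, 0.001), "S")$ratio, 2)
  expect_equal(parent_offspring_ratio(fake(0.10, 0.001), fake(0.10, 0.001), "S")$ratio, 1)
})

test_that("rho = 1 parents inherit the full own effect; rho = 0 parents none", {
  base <- function(rho) {
    sim_config(
      n_per_ancestry = c(EUR = 15000), followup_years = 25,
      parents = list(rho = rho, age_gap_mean = 28, age_gap_sd = 5)
    )
  }
  for (rho in c(0, 1 - 1e-9)) {
    sim <- simulate_cohort(base(rho), seed = 505)
    d <- prsbench:::mortality_design(sim$cohort, sim$scores, "parental")
    fit <- survival::coxph(survival::Surv(d$time, d$event) ~ d$S[, "PRS_CAD"] + d$Z)
    b <- coef(fit)[1]
    se <- sqrt(vcov(fit)[1, 1])
    want <- if (rho == 0) 0 else 0.2
    expect_lt(abs(b - want), 3 * se + 0.015)
  }
  expect_error(
    simulate_cohort(sim_config(parents = list(rho = 1.2, age_gap_mean = 28, age_gap_sd = 5)), 1),
    "rho|correlation|inside"
  )
})
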