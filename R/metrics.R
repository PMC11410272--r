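# Per-SD effect-size metrics. All disease and quantitative effects are
# expressed per standard deviation of the PRS after standardisation within
# the evaluation subgroup, with Wald 95% confidence intervals.

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Standardise a PRS to zero mean and unit SD in a reference subgroup
#'
#' The affine map estimated in the reference subgroup is applied to all
#' individuals, so "per SD" means per reference-subgroup SD. When the
#' reference is an ancestry subgroup, other ancestries will in general not
#' have unit SD after the map.
#'
#' The scale factor is the population (denominator-n) SD of the reference,
#' so the standardised reference has SD exactly 1; at evaluation-cohort
#' sizes this is indistinguishable from the n-1 convention used for the
#' descriptive distribution tables.
#'
#' @param x numeric raw score vector.
#' @param reference logical vector (same length) selecting the reference
#'   subgroup; default: all individuals.
#' @return Numeric vector with mean 0 and SD 1 within the reference.
#' @export
standardize_prs <- function(x, reference = NULL) {
  if (is.null(reference)) reference <- rep(TRUE, length(x))
  stopifnot(is.logical(reference), length(reference) == length(x))
  r <- x[reference & !is.na(x)]
  if (length(r) < 2) stopf("reference subgroup needs at least 2 individuals")
  s <- pop_sd(r)
  if (!is.finite(s) || s == 0) stopf("degenerate score: zero variance in the reference subgroup")
  (x - mean(r)) / s
}

effect_estimate <- function(metric, estimate, se, n_total, n_cases = NA_integer_,
                            stratum = list(), log_scale = metric %in% c("or_per_sd", "hr_per_sd"),
                            extra = list(), gated = FALSE, gate_reason = NULL) {
  est <- estimate
  if (log_scale && !gated) {
    ci <- exp(estimate + c(-1, 1) * qnorm(0.975) * se)
    est <- exp(estimate)
  } else if (!gated) {
    ci <- estimate + c(-1, 1) * qnorm(0.975) * se
  } else {
    est <- NA_real_
    ci <- c(NA_real_, NA_real_)
    se <- NA_real_
  }
  structure(
    c(list(
      metric = metric, estimate = est,
      log_estimate = if (log_scale && !gated) estimate else NA_real_,
      se = se, ci_low = ci[1], ci_high = ci[2],
      n_total = as.integer(n_total), n_cases = as.integer(n_cases),
      stratum = stratum, log_scale = log_scale,
      gated = gated, gate_reason = gate_reason
    ), extra),
    class = "prs_effect"
  )
}

#' @export
print.prs_effect <- function(x, ...) {
  lab <- paste(unlist(x$stratum), collapse = ", ")
  if (isTRUE(x$gated)) {
    cat(sprintf(
      "<%s>%s suppressed (%s); n = %d, cases = %d\n", x$metric,
      if (nzchar(lab)) paste0(" [", lab, "]") else "", x$gate_reason, x$n_total, x$n_cases
    ))
  } else {
    cat(sprintf(
      "<%s>%s %.4g (95%% CI %.4g-%.4g); n = %d%s\n", x$metric,
      if (nzchar(lab)) paste0(" [", lab, "]") else "",
      x$estimate, x$ci_low, x$ci_high, x$n_total,
      if (!is.na(x$n_cases)) sprintf(", cases = %d", x$n_cases) else ""
    ))
  }
  invisible(x)
}

# covariate model matrix shared by the regression metrics; sex is dropped
# automatically when constant (sex-restricted traits), individuals with
# missing sex are excluded from sex-adjusted models
covariate_frame <- function(frame, covariates) {
  keep <- rep(TRUE, nrow(frame))
  cols <- list()
  if ("sex" %in% covariates) {
    if (length(unique(frame$sex[!is.na(frame$sex)])) > 1) {
      keep <- keep & !is.na(frame$sex)
      cols$sex_male <- as.numeric(frame$sex == "male")
    }
  }
  if ("age_at_assessment" %in% covariates) {
    keep <- keep & is.finite(frame$age_at_assessment)
    cols$age <- frame$age_at_assessment
  }
  X <- if (length(cols)) do.call(cbind, cols) else NULL
  list(X = X, keep = keep)
}

detect_separation <- function(fit, y) {
  mu <- fit$fitted.values
  sep <- all(mu[y == 1] > 1 - 1e-7) && all(mu[y == 0] < 1e-7)
  sep || !fit$converged || abs(coef(fit)[["prs"]]) > 15
}

#' Odds ratio per SD of PRS from covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic regression of case status on the
#' standardised PRS, adjusting by default for age at first assessment and
#' sex. The PRS coefficient is exponentiated; the 95% CI is Wald, on the
#' log-odds scale.
#'
#' @param frame a `prs_frame` from [align()] with a binary phenotype.
#' @param covariates character subset of
#'   `c("age_at_assessment", "sex")`; sex is dropped automatically when
#'   constant within the frame.
#' @param standardize standardise the PRS within the frame first (default).
#' @param min_cases suppress the estimate (keeping counts) when the case
#'   count is below this gate; `0` disables gating.
#' @param stratum named list of labels stored with the estimate.
#' @return A `prs_effect` with metric `"or_per_sd"`.
#' @export
or_per_sd <- function(frame, covariates = c("age_at_assessment", "sex"),
                      standardize = TRUE, min_cases = 0, stratum = list()) {
  y <- frame$case
  if (sum(y == 1) < 1 || sum(y == 0) < 1) stopf("need at least one case and one control")
  stratum <- modifyList(list(trait = attr(frame, "trait_code"), score = attr(frame, "score_name")), stratum)
  if (sum(y == 1) < min_cases) {
    return(effect_estimate("or_per_sd", NA, NA, length(y), sum(y == 1),
      stratum = stratum, gated = TRUE,
      gate_reason = sprintf("fewer than %d cases", min_cases)
    ))
  }
  cf <- covariate_frame(frame, covariates)
  prs <- frame$prs[cf$keep]
  if (standardize) prs <- standardize_prs(prs)
  dat <- data.frame(y = y[cf$keep], prs = prs)
  if (!is.null(cf$X)) dat <- cbind(dat, as.data.frame(cf$X[cf$keep, , drop = FALSE]))
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial(),
    control = list(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged) stopf("logistic regression did not converge")
  if (detect_separation(fit, dat$y)) stopf("complete separation: PRS perfectly predicts case status")
  b <- coef(fit)[["prs"]]
  se <- sqrt(vcov(fit)["prs", "prs"])
  effect_estimate("or_per_sd", b, se, nrow(dat), sum(dat$y == 1), stratum = stratum)
}

# build the Surv() pieces for age-scale analyses; lifetime mode enters at
# age 0 and uses all recorded diagnoses, incident mode left-truncates at
# assessment and drops prevalent cases
surv_pieces <- function(frame, mode = c("lifetime", "incident")) {
  mode <- match.arg(mode)
  event <- frame$case == 1L
  time <- ifelse(event, frame$event_age, frame$censor_age)
  keep <- is.finite(time) & time > 0
  if (mode == "incident") {
    prevalent <- event & frame$event_age <= frame$age_at_assessment
    keep <- keep & !prevalent & time > frame$age_at_assessment
    list(
      start = frame$age_at_assessment[keep], time = time[keep],
      event = event[keep], keep = keep, n_prevalent = sum(prevalent)
    )
  } else {
    list(start = NULL, time = time[keep], event = event[keep], keep = keep, n_prevalent = 0L)
  }
}

#' Hazard ratio per SD of PRS from Cox regression
#'
#' Cox partial-likelihood estimate of the PRS log hazard ratio, Breslow tie
#' handling, exponentiated with a Wald 95% CI. On the age timescale the
#' lifetime mode enters individuals at age 0; the incident mode
#' left-truncates at age at first assessment and excludes prevalent cases.
#'
#' @inheritParams or_per_sd
#' @param timescale `"age"` or `"followup"` (time since assessment).
#' @param mode `"lifetime"` or `"incident"` (age timescale only).
#' @param ties passed to [survival::coxph()] (default `"breslow"`).
#' @return A `prs_effect` with metric `"hr_per_sd"`.
#' @export
hr_per_sd <- function(frame, timescale = c("age", "followup"),
                      covariates = c("sex"), mode = attr(frame, "incidence_mode") %||% "lifetime",
                      standardize = TRUE, min_cases = 0, ties = "breslow", stratum = list()) {
  timescale <- match.arg(timescale)
  stratum <- modifyList(list(trait = attr(frame, "trait_code"), score = attr(frame, "score_name")), stratum)
  if (timescale == "age") {
    sp <- surv_pieces(frame, mode)
  } else {
    event <- frame$case == 1L & frame$event_age > frame$age_at_assessment
    time <- ifelse(event, frame$event_age, frame$censor_age) - frame$age_at_assessment
    keep <- is.finite(time) & time > 0 & !(frame$case == 1L & frame$event_age <= frame$age_at_assessment)
    sp <- list(start = NULL, time = time[keep], event = event[keep], keep = keep)
  }
  if (!any(sp$event)) stopf("no events: all observations censored")
  if (sum(sp$event) < min_cases) {
    return(effect_estimate("hr_per_sd", NA, NA, sum(sp$keep), sum(sp$event),
      stratum = stratum, gated = TRUE,
      gate_reason = sprintf("fewer than %d events", min_cases)
    ))
  }
  prs <- frame$prs[sp$keep]
  if (standardize) prs <- standardize_prs(prs)
  if (sd(prs) == 0) stopf("degenerate score: zero variance")
  cf <- covariate_frame(frame[sp$keep, , drop = FALSE], setdiff(covariates, if (timescale == "age") "age_at_assessment" else character()))
  X <- cbind(prs = prs, cf$X)
  ss <- if (is.null(sp$start)) Surv(sp$time, sp$event) else Surv(sp$start, sp$time, sp$event)
  fit <- coxph(ss ~ X, ties = ties, control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  b <- unname(coef(fit)[1]) # the PRS term is the first design column
  if (!is.finite(b) || abs(b) > 15) stopf("monotone partial likelihood: log-HR diverges")
  se <- sqrt(vcov(fit)[1, 1])
  effect_estimate("hr_per_sd", b, se, sum(sp$keep), sum(sp$event),
    stratum = stratum,
    extra = list(timescale = timescale, mode = if (timescale == "age") mode else "incident")
  )
}

#' Effect per SD of PRS on a standardised quantitative trait
#'
#' Ordinary least squares of the standardised trait on the standardised
#' PRS, adjusting by default for age and sex. The trait is standardised to
#' zero mean and unit variance (within each sex separately and then pooled
#' when `sex_standardize = TRUE`, as for sex-stratified reporting). `r2` is
#' the increment in model R-squared from adding the PRS to the
#' covariate-only model.
#'
#' @inheritParams or_per_sd
#' @param sex_standardize standardise the trait within each sex before
#'   pooling.
#' @return A `prs_effect` with metric `"beta_per_sd"`; the incremental
#'   R-squared is in `$r2`.
#' @export
beta_per_sd <- function(frame, covariates = c("age_at_assessment", "sex"),
                        sex_standardize = FALSE, standardize = TRUE, stratum = list()) {
  v <- frame$value
  if (sd(v, na.rm = TRUE) == 0) stopf("constant trait: zero variance")
  stratum <- modifyList(list(trait = attr(frame, "trait_code"), score = attr(frame, "score_name")), stratum)
  cf <- covariate_frame(frame, covariates)
  keep <- cf$keep & is.finite(v)
  if (sex_standardize) keep <- keep & !is.na(frame$sex)
  y <- v[keep]
  if (sex_standardize) {
    sx <- frame$sex[keep]
    for (g in unique(sx)) {
      idx <- sx == g
      if (pop_sd(y[idx]) == 0) stopf("constant trait within sex '%s'", g)
      y[idx] <- (y[idx] - mean(y[idx])) / pop_sd(y[idx])
    }
  } else {
    y <- (y - mean(y)) / pop_sd(y)
  }
  prs <- frame$prs[keep]
  if (standardize) prs <- standardize_prs(prs)
  dat <- data.frame(y = y, prs = prs)
  if (!is.null(cf$X)) dat <- cbind(dat, as.data.frame(cf$X[keep, , drop = FALSE]))
  fit <- lm(y ~ ., data = dat)
  fit0 <- lm(y ~ ., data = dat[, setdiff(names(dat), "prs"), drop = FALSE])
  b <- coef(fit)[["prs"]]
  # a perfect fit (trait identical to the score) is a legitimate degenerate
  # input here; silence the "essentially perfect fit" note
  se <- sqrt(suppressWarnings(vcov(fit)["prs", "prs"]))
  r2 <- suppressWarnings(summary(fit)$r.squared - summary(fit0)$r.squared)
  effect_estimate("beta_per_sd", b, se, nrow(dat),
    stratum = stratum, log_scale = FALSE,
    extra = list(r2 = r2, sex_standardized = sex_standardize)
  )
}

# Mann-Whitney AUC with ties counted 0.5, via midranks: O(n log n)
auc_stat <- function(cases, controls) {
  n1 <- length(cases)
  n0 <- length(controls)
  r <- rank(c(cases, controls), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of the PRS alone
#'
#' The probability that a randomly chosen case has a higher PRS than a
#' randomly chosen control (Mann-Whitney concordance; ties count 0.5),
#' computed with no covariates. The default 95% CI is the DeLong analytic
#' interval; a percentile-bootstrap interval is available.
#'
#' @inheritParams or_per_sd
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_bootstrap bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap CI.
#' @return A `prs_effect` with metric `"auc"`.
#' @export
auc_prs <- function(frame, min_cases = 0, ci_method = c("delong", "bootstrap"),
                    n_bootstrap = 2000, seed = 1, stratum = list()) {
  ci_method <- match.arg(ci_method)
  stratum <- modifyList(list(trait = attr(frame, "trait_code"), score = attr(frame, "score_name")), stratum)
  keep <- !is.na(frame$prs) & !is.na(frame$case)
  x <- frame$prs[keep]
  y <- frame$case[keep]
  cases <- x[y == 1]
  controls <- x[y == 0]
  if (!length(cases) || !length(controls)) stopf("need at least one case and one control")
  if (length(cases) < min_cases) {
    return(effect_estimate("auc", NA, NA, length(x), length(cases),
      stratum = stratum, log_scale = FALSE, gated = TRUE,
      gate_reason = sprintf("fewer than %d cases", min_cases)
    ))
  }
  a <- auc_stat(cases, controls)
  if (ci_method == "delong") {
    # DeLong structural components: V10_i = P(case_i > control) etc.
    v10 <- vapply(cases, function(ci) mean((ci > controls) + 0.5 * (ci == controls)), 0)
    v01 <- vapply(controls, function(cj) mean((cases > cj) + 0.5 * (cases == cj)), 0)
    se <- sqrt(var(v10) / length(cases) + var(v01) / length(controls))
    ci <- pmin(1, pmax(0, a + c(-1, 1) * qnorm(0.975) * se))
  } else {
    boot <- with_substream(seed, "auc_ci", {
      replicate(n_bootstrap, {
        auc_stat(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
      })
    })
    se <- sd(boot)
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  out <- effect_estimate("auc", a, se, length(x), length(cases),
    stratum = stratum, log_scale = FALSE
  )
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out
}

#' Effective sample size of a case-control meta-analysis
#'
#' `4 * sum(n_j * c_j * (1 - c_j))` over constituent studies with total
#' sizes `n_j` and case fractions `c_j`.
#'
#' @param n numeric vector of per-study total sample sizes (> 0).
#' @param case_fraction numeric vector of per-study case fractions, each
#'   strictly inside (0, 1).
#' @return The effective sample size (0 for empty input).
#' @export
effective_sample_size_meta <- function(n, case_fraction) {
  stopifnot(length(n) == length(case_fraction))
  if (!length(n)) return(0)
  if (any(n <= 0)) stopf("per-study sample sizes must be positive")
  if (any(case_fraction <= 0 | case_fraction >= 1)) stopf("case fractions must be strictly inside (0, 1)")
  4 * sum(n * case_fraction * (1 - case_fraction))
}

#' Effective sample size of a single case-control study
#'
#' `4 / (1/n0 + 1/n1)` for `n0` controls and `n1` cases.
#'
#' @param n_controls,n_cases positive counts.
#' @return The effective sample size.
#' @export
effective_sample_size_cc <- function(n_controls, n_cases) {
  if (n_controls <= 0 || n_cases <= 0) stopf("both counts must be positive")
  4 / (1 / n_controls + 1 / n_cases)
}
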