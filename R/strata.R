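# Age-window and sex-stratified effect sizes and their difference tests.
# Strata are disjoint individuals, so difference SEs combine independently.

#' PRS hazard ratio within an age-at-assessment window
#'
#' Restricts to individuals first assessed within `age_band`, excludes
#' prevalent cases (diagnosed on or before assessment), counts only events
#' within `horizon_years` of assessment (later events are censored at the
#' horizon), and fits a Cox model per SD of PRS on the follow-up timescale.
#'
#' @param frame a `prs_frame` with a binary phenotype.
#' @param age_band `c(min, max)`: assessment age in `[min, max]` (e.g.
#'   `c(40, 49)` or `c(60, 69)`).
#' @param horizon_years incident horizon after assessment (default 10).
#' @param covariates covariates in addition to the PRS (default sex and
#'   age at assessment, linear within the band).
#' @param min_events gate: suppressed below this many incident events.
#' @return A `prs_effect` with metric `"hr_per_sd"` and the window recorded
#'   in its stratum.
#' @export
age_window_hr <- function(frame, age_band, horizon_years = 10,
                          covariates = c("age_at_assessment", "sex"), min_events = 1) {
  stopifnot(length(age_band) == 2, age_band[1] < age_band[2])
  inb <- frame$age_at_assessment >= age_band[1] & frame$age_at_assessment <= age_band[2]
  sub <- frame[inb & !is.na(inb), , drop = FALSE]
  if (!nrow(sub)) stopf("no individuals assessed at ages %g-%g", age_band[1], age_band[2])
  prevalent <- sub$case == 1L & sub$event_age <= sub$age_at_assessment
  sub <- sub[!prevalent, , drop = FALSE]
  horizon_age <- sub$age_at_assessment + horizon_years
  end_age <- pmin(ifelse(sub$case == 1L, sub$event_age, Inf), sub$censor_age, horizon_age)
  event <- sub$case == 1L & sub$event_age <= pmin(sub$censor_age, horizon_age)
  time <- end_age - sub$age_at_assessment
  keep <- is.finite(time) & time > 0
  sub <- sub[keep, , drop = FALSE]
  time <- time[keep]
  event <- event[keep]
  stratum <- list(
    trait = attr(frame, "trait_code"), score = attr(frame, "score_name"),
    age_band = sprintf("%g-%g", age_band[1], age_band[2]),
    horizon_years = horizon_years
  )
  if (sum(event) < max(1, min_events)) {
    return(effect_estimate("hr_per_sd", NA, NA, nrow(sub), sum(event),
      stratum = stratum, gated = TRUE,
      gate_reason = sprintf("%d incident events within the %g-year horizon", sum(event), horizon_years)
    ))
  }
  prs <- standardize_prs(sub$prs)
  cf <- covariate_frame(sub, covariates)
  X <- cbind(prs = prs, cf$X)
  fit <- coxph(Surv(time, event) ~ X, ties = "breslow")
  b <- coef(fit)[["Xprs"]]
  se <- sqrt(vcov(fit)["Xprs", "Xprs"])
  effect_estimate("hr_per_sd", b, se, nrow(sub), sum(event),
    stratum = stratum,
    extra = list(timescale = "followup", n_prevalent_excluded = sum(prevalent))
  )
}

#' Difference in PRS effect between two age windows
#'
#' Difference of log hazard ratios with independent-strata SE
#' `sqrt(se1^2 + se2^2)`, Wald 95% CI and two-tailed p.
#'
#' @param effect_young,effect_old `prs_effect`s from [age_window_hr()].
#' @return List with `difference` (log-HR scale), `se`, `ci_low`,
#'   `ci_high`, `z`, `p`.
#' @export
age_group_difference <- function(effect_young, effect_old) {
  if (isTRUE(effect_young$gated) || isTRUE(effect_old$gated)) {
    stopf("both age-window estimates must be gated in")
  }
  d <- effect_young$log_estimate - effect_old$log_estimate
  se <- sqrt(effect_young$se^2 + effect_old$se^2)
  z <- d / se
  list(
    difference = d, se = se,
    ci_low = d - qnorm(0.975) * se, ci_high = d + qnorm(0.975) * se,
    z = z, p = z_pvalue(z),
    stratum_young = effect_young$stratum$age_band,
    stratum_old = effect_old$stratum$age_band
  )
}

#' Sex-stratified (or pooled) PRS effect
#'
#' Computes the chosen metric within one sex stratum with age adjustment
#' only (sex is constant within a stratum). For quantitative traits the
#' trait is standardised to zero mean and unit variance within each sex
#' separately; the `"all"` stratum pools the within-sex standardised trait,
#' which changes the effect scale relative to unstratified reporting.
#'
#' @param frame a `prs_frame`.
#' @param sex `"female"`, `"male"` or `"all"`.
#' @param metric `"or"`, `"beta"` or `"auc"`.
#' @param min_cases gate for disease metrics.
#' @return A `prs_effect` with the sex stratum recorded.
#' @export
sex_stratified_effect <- function(frame, sex = c("all", "female", "male"),
                                  metric = c("or", "beta", "auc"), min_cases = 0) {
  sex <- match.arg(sex)
  metric <- match.arg(metric)
  restrict <- attr(frame, "sex_restriction")
  if (!is.null(restrict) && sex != "all" && sex != restrict) {
    stopf("trait is restricted to %ss; '%s' stratum not estimable", restrict, sex)
  }
  sub <- if (sex == "all") frame[!is.na(frame$sex), , drop = FALSE] else frame[!is.na(frame$sex) & frame$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stopf("empty sex stratum '%s'", sex)
  attr(sub, "trait_code") <- attr(frame, "trait_code")
  attr(sub, "score_name") <- attr(frame, "score_name")
  stratum <- list(sex = sex)
  if (metric == "or") {
    or_per_sd(sub, covariates = "age_at_assessment", min_cases = min_cases, stratum = stratum)
  } else if (metric == "auc") {
    auc_prs(sub, min_cases = min_cases, stratum = stratum)
  } else {
    beta_per_sd(sub,
      covariates = "age_at_assessment",
      sex_standardize = (sex == "all"), stratum = stratum
    )
  }
}

#' Two-tailed test for a female-male difference in PRS effect
#'
#' z-test on the difference of effects (log scale for ratio metrics) with
#' independent SEs; the strata are disjoint individuals. Returns the star
#' annotation used in stratified summary tables (`*` p<0.05, `**` p<0.01,
#' `***` p<0.001).
#'
#' @param effect_f,effect_m `prs_effect`s for the female and male strata.
#' @return List with `difference`, `se`, `z`, `p`, `stars`.
#' @export
sex_difference_test <- function(effect_f, effect_m) {
  if (isTRUE(effect_f$gated) || isTRUE(effect_m$gated)) stopf("both sex-stratum estimates must be gated in")
  vf <- if (isTRUE(effect_f$log_scale)) effect_f$log_estimate else effect_f$estimate
  vm <- if (isTRUE(effect_m$log_scale)) effect_m$log_estimate else effect_m$estimate
  d <- vf - vm
  se <- sqrt(effect_f$se^2 + effect_m$se^2)
  z <- d / se
  p <- z_pvalue(z)
  list(difference = d, se = se, z = z, p = p, stars = p_stars(p))
}
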