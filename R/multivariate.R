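# Cross-PRS correlation structure and multi-PRS all-cause mortality
# modelling on participants' own and parental lifespans.

#' Pairwise Pearson correlations between PRSs
#'
#' Pairwise complete-case correlations within an evaluation subgroup. One
#' triangle is computed and mirrored, so the stored matrix is exactly
#' symmetric. Constant scores are flagged and their rows/columns set `NA`.
#'
#' @param scores a [score_set()].
#' @param subgroup optional character vector of individual ids (e.g. one
#'   ancestry group) to restrict to.
#' @return A `prs_cormat`: the correlation matrix with a `degenerate`
#'   attribute naming constant scores.
#' @export
prs_correlation_matrix <- function(scores, subgroup = NULL) {
  sc <- as.data.frame(scores)
  if (!is.null(subgroup)) sc <- sc[sc$individual_id %in% subgroup, , drop = FALSE]
  cols <- setdiff(names(sc), "individual_id")
  if (length(cols) < 2) stopf("need at least two scores")
  if (nrow(sc) < 3) stopf("need at least three individuals")
  M <- as.matrix(sc[, cols, drop = FALSE])
  degenerate <- cols[apply(M, 2, function(x) sd(x, na.rm = TRUE) == 0)]
  R <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  R[degenerate, ] <- NA_real_
  R[, degenerate] <- NA_real_
  diag(R) <- 1
  R[lower.tri(R)] <- t(R)[lower.tri(R)] # mirror one triangle exactly
  structure(R, class = c("prs_cormat", class(R)), degenerate = degenerate)
}

#' Dendrogram leaf order of a PRS correlation matrix
#'
#' Hierarchical agglomerative clustering of the correlation rows, complete
#' linkage on Euclidean distance, as used to order release-style
#' correlation heatmaps. Rows are sorted by name before clustering so the
#' order is invariant to input permutation.
#'
#' @param cormat a `prs_cormat` from [prs_correlation_matrix()].
#' @return Character vector: score names in dendrogram leaf order.
#' @export
cluster_order <- function(cormat) {
  if (any(is.na(cormat))) stopf("correlation matrix has undefined entries")
  nm <- sort(rownames(cormat))
  R <- cormat[nm, nm, drop = FALSE]
  hc <- hclust(dist(R, method = "euclidean"), method = "complete")
  nm[hc$order]
}

mortality_design <- function(cohort, scores, target = c("own", "parental"),
                             timescale = c("age", "followup")) {
  target <- match.arg(target)
  timescale <- match.arg(timescale)
  co <- as.data.frame(cohort)
  sc <- as.data.frame(scores)
  cols <- setdiff(names(sc), "individual_id")
  if (target == "own") {
    idx <- match(co$individual_id, sc$individual_id)
    event <- !is.na(co$death_age) & co$death_age <= co$censor_age
    keep <- !is.na(idx) & is.finite(co$censor_age) &
      co$censor_age > co$age_at_assessment & !is.na(co$sex)
    if (timescale == "age") {
      # left truncation at assessment; age is the timescale, not a covariate
      Z <- cbind(sex_male = as.numeric(co$sex == "male"))
      list(
        start = co$age_at_assessment[keep], time = co$censor_age[keep],
        event = event[keep],
        S = as.matrix(sc[idx[keep], cols, drop = FALSE]),
        Z = Z[keep, , drop = FALSE], target = target
      )
    } else {
      time <- co$censor_age - co$age_at_assessment
      Z <- cbind(age = co$age_at_assessment, sex_male = as.numeric(co$sex == "male"))
      list(
        start = NULL, time = time[keep], event = event[keep],
        S = as.matrix(sc[idx[keep], cols, drop = FALSE]),
        Z = Z[keep, , drop = FALSE], target = target
      )
    }
  } else {
    pa <- attr(cohort, "parents")
    if (is.null(pa) || !nrow(pa)) stopf("cohort has no parental records")
    idx <- match(pa$individual_id, sc$individual_id)
    ci <- match(pa$individual_id, co$individual_id)
    time <- as.numeric(pa$parent_age)
    event <- pa$parent_dead == 1
    keep <- !is.na(idx) & !is.na(ci) & is.finite(time) & time > 0
    Z <- cbind(
      age = co$age_at_assessment[ci],
      parent_male = as.numeric(tolower(as.character(pa$parent_sex)) == "male")
    )
    list(
      start = NULL, time = time[keep], event = event[keep],
      S = as.matrix(sc[idx[keep], cols, drop = FALSE]),
      Z = Z[keep, , drop = FALSE], target = target
    )
  }
}

wald_p <- function(fit, name) {
  b <- coef(fit)[[name]]
  se <- sqrt(vcov(fit)[name, name])
  z_pvalue(b / se)
}

#' Forward-stepwise multi-PRS Cox model of all-cause mortality
#'
#' Stepwise selection over candidate PRSs of a Cox model of time from first
#' assessment to death from any cause (`target = "own"`), or of parental
#' lifespan with maternal and paternal records entered as separate
#' observations (`target = "parental"`, adjusted for the participant's age
#' at first assessment and the parent's sex; the offspring's PRS is the
#' predictor). Each iteration adds the candidate with the smallest Wald p
#' below `entry_p` (ties broken by p then name), then removes any selected
#' score whose p exceeds `removal_p`, until a fixpoint. An empty selected
#' set is a valid result. Baseline covariates are always kept.
#'
#' @param cohort a [cohort_table()] (with parental records for
#'   `target = "parental"`).
#' @param scores a [score_set()]; each candidate is standardised to unit SD
#'   before fitting, so coefficients are log-HR per SD.
#' @param target `"own"` or `"parental"`.
#' @param timescale for the own-mortality model: `"age"` (default; left
#'   truncation at assessment, so own and parental hazards share the age
#'   axis) or `"followup"` (time since assessment with age at assessment as
#'   a covariate).
#' @param candidates candidate score names (default: all columns).
#' @param entry_p,removal_p stepwise thresholds (default 0.001).
#' @param c_diff_boot paired-bootstrap resamples for the CI of the change
#'   in Harrell's C over the covariate-only model (0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @return A `prs_mortality_model`: selected scores, per-score log-HR with
#'   CI, Harrell's C of the full and covariate-only models with the
#'   difference and its CI, and Royston's explained variation.
#' @export
stepwise_mortality <- function(cohort, scores, target = c("own", "parental"),
                               timescale = c("age", "followup"),
                               candidates = NULL, entry_p = 0.001, removal_p = 0.001,
                               c_diff_boot = 200, seed = 1) {
  target <- match.arg(target)
  d <- mortality_design(cohort, scores, target, match.arg(timescale))
  cols <- colnames(d$S)
  candidates <- sort(candidates %||% cols)
  stopifnot(all(candidates %in% cols))
  S <- apply(d$S[, candidates, drop = FALSE], 2, standardize_prs)
  ss <- if (is.null(d$start)) Surv(d$time, d$event) else Surv(d$start, d$time, d$event)
  fit_with <- function(sel) {
    X <- cbind(d$Z, S[, sel, drop = FALSE])
    coxph(ss ~ X, ties = "breslow", control = survival::coxph.control(iter.max = 100))
  }
  selected <- character()
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      ps <- vapply(pool, function(s) {
        tryCatch(wald_p(fit_with(c(selected, s)), paste0("X", s)), error = function(e) NA_real_)
      }, 0)
      ps <- ps[!is.na(ps)]
      if (length(ps) && min(ps) < entry_p) {
        best <- names(ps)[order(ps, names(ps))][1]
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- fit_with(selected)
      ps <- vapply(selected, function(s) wald_p(fit, paste0("X", s)), 0)
      if (max(ps) > removal_p) {
        worst <- names(ps)[order(-ps, names(ps))][1]
        selected <- setdiff(selected, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected <- sort(selected)
  fit_full <- fit_with(selected)
  fit_red <- fit_with(character())
  coefs <- NULL
  if (length(selected)) {
    nm <- paste0("X", selected)
    b <- coef(fit_full)[nm]
    se <- sqrt(diag(vcov(fit_full))[nm])
    coefs <- data.frame(
      score = selected, log_hr = unname(b), se = unname(se),
      hr = exp(unname(b)),
      ci_low = exp(unname(b) - qnorm(0.975) * se),
      ci_high = exp(unname(b) + qnorm(0.975) * se),
      row.names = NULL
    )
  }
  pred_full <- drop(predict(fit_full, type = "lp"))
  pred_red <- drop(predict(fit_red, type = "lp"))
  c_full <- harrells_c(pred_full, d$time, d$event, start = d$start)
  c_red <- harrells_c(pred_red, d$time, d$event, start = d$start)
  c_diff <- harrells_c_diff(pred_full, pred_red, d$time, d$event,
    start = d$start, n_boot = c_diff_boot, seed = seed
  )
  # Royston's explained variation for the PRS-only prognostic index
  prs_index <- if (length(selected)) drop(S[, selected, drop = FALSE] %*% coef(fit_full)[paste0("X", selected)]) else rep(0, length(d$time))
  structure(list(
    target = target, selected = selected, coefficients = coefs,
    baseline_covariates = colnames(d$Z),
    entry_p = entry_p, removal_p = removal_p,
    n = length(d$time), n_events = sum(d$event),
    c_full = c_full$c, c_reduced = c_red$c,
    c_diff = c_diff$difference, c_diff_ci = c(c_diff$ci_low, c_diff$ci_high),
    royston_r2 = royston_r2(prs_index, d$time, d$event, start = d$start),
    seed = seed
  ), class = "prs_mortality_model")
}

#' @export
print.prs_mortality_model <- function(x, ...) {
  cat(sprintf(
    "<prs_mortality_model> %s mortality: %d selected of %s candidates; n = %d, deaths = %d\n",
    x$target, length(x$selected), "all", x$n, x$n_events
  ))
  if (!is.null(x$coefficients)) print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf(
    "  Harrell's C %.4f vs %.4f (change %.4f); Royston R2_D %.4f\n",
    x$c_full, x$c_reduced, x$c_diff, x$royston_r2
  ))
  invisible(x)
}

#' Harrell's concordance for risk predictions
#'
#' Fraction of usable pairs (an event versus a later event or later
#' censoring) in which the subject with the higher predicted risk has the
#' earlier event; ties in the prediction count 0.5.
#'
#' @param pred numeric risk predictions (higher = higher risk).
#' @param time,event follow-up times and event indicators.
#' @param start optional left-truncation entry times.
#' @return List with `c`, `se` and a Wald 95% CI.
#' @export
harrells_c <- function(pred, time, event, start = NULL) {
  if (sum(event) < 1) stopf("no usable pairs: no events")
  ss <- if (is.null(start)) Surv(time, event) else Surv(start, time, event)
  cc <- concordance(ss ~ pred, reverse = TRUE)
  se <- sqrt(cc$var)
  list(
    c = unname(cc$concordance), se = se,
    ci_low = unname(cc$concordance - qnorm(0.975) * se),
    ci_high = unname(cc$concordance + qnorm(0.975) * se)
  )
}

#' Paired-bootstrap change in Harrell's C between nested models
#'
#' Resamples subjects with replacement (the same resample for both
#' prediction vectors) and recomputes the difference in C.
#'
#' @param pred_full,pred_reduced risk predictions of the two models on the
#'   same subjects.
#' @inheritParams harrells_c
#' @param start optional left-truncation entry times.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the CI).
#' @param seed RNG seed.
#' @return List with `difference`, `ci_low`, `ci_high`, `seed`.
#' @export
harrells_c_diff <- function(pred_full, pred_reduced, time, event, start = NULL,
                            n_boot = 1000, seed = 1) {
  d0 <- harrells_c(pred_full, time, event, start)$c -
    harrells_c(pred_reduced, time, event, start)$c
  if (n_boot < 1) {
    return(list(difference = d0, ci_low = NA_real_, ci_high = NA_real_, seed = seed))
  }
  n <- length(time)
  diffs <- with_substream(seed, "harrells_c_diff", {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) < 2) return(NA_real_)
      harrells_c(pred_full[idx], time[idx], event[idx], start[idx]) $c -
        harrells_c(pred_reduced[idx], time[idx], event[idx], start[idx])$c
    }, 0)
  })
  diffs <- diffs[!is.na(diffs)]
  ci <- unname(quantile(diffs, c(0.025, 0.975)))
  list(difference = d0, ci_low = ci[1], ci_high = ci[2], seed = seed)
}

#' Royston and Sauerbrei's explained variation for a survival model
#'
#' The D statistic is the Cox coefficient of the rank-based (Blom) normal
#' scores of the prognostic index scaled by `kappa = sqrt(8/pi)`;
#' explained variation is `R2_D = (D^2/kappa^2) / (D^2/kappa^2 + pi^2/6)`.
#' A constant prognostic index gives 0.
#'
#' @param pred prognostic index (linear predictor) per subject.
#' @param time,event follow-up times and event indicators.
#' @param start optional left-truncation entry times.
#' @return `R2_D` in `[0, 1)`.
#' @export
royston_r2 <- function(pred, time, event, start = NULL) {
  if (sd(pred) == 0) return(0)
  n <- length(pred)
  rk <- rank(pred, ties.method = "average")
  z <- qnorm((rk - 3 / 8) / (n + 1 / 4)) # Blom normal scores
  kappa <- sqrt(8 / pi)
  ss <- if (is.null(start)) Surv(time, event) else Surv(start, time, event)
  fit <- coxph(ss ~ I(z / kappa), ties = "breslow")
  D <- unname(coef(fit)[1])
  (D^2 / kappa^2) / (D^2 / kappa^2 + pi^2 / 6)
}

#' Ratio of own to parental PRS log hazard ratios
#'
#' For a score selected in both the own-mortality and parental-mortality
#' models, the ratio of the own log-HR to the parental log-HR with a
#' delta-method 95% CI (independent fits). Under a parent-offspring PRS
#' correlation of 0.5 the expected ratio is 2.
#'
#' @param model_own,model_parental `prs_mortality_model`s.
#' @param score score name present in both models.
#' @return List with `ratio`, `se`, `ci_low`, `ci_high` and the two
#'   log-HRs; an error if the parental log-HR is indistinguishable from 0.
#' @export
parent_offspring_ratio <- function(model_own, model_parental, score) {
  get1 <- function(m) {
    if (is.null(m$coefficients) || !(score %in% m$coefficients$score)) {
      stopf("score '%s' not in the %s-mortality model", score, m$target)
    }
    m$coefficients[m$coefficients$score == score, ]
  }
  o <- get1(model_own)
  p <- get1(model_parental)
  if (abs(p$log_hr) < 2 * p$se) {
    stopf("parental log-HR for '%s' is not distinguishable from zero; ratio undefined", score)
  }
  r <- o$log_hr / p$log_hr
  se <- sqrt(o$se^2 / p$log_hr^2 + o$log_hr^2 * p$se^2 / p$log_hr^4)
  list(
    score = score, ratio = r, se = se,
    ci_low = r - qnorm(0.975) * se, ci_high = r + qnorm(0.975) * se,
    log_hr_own = o$log_hr, log_hr_parental = p$log_hr
  )
}
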