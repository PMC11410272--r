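# Head-to-head PRS comparison by paired bootstrap, relative ancestry
# performance change with delta-method intervals, and cross-trait pooling.

# one fast log-scale metric evaluation on a row subset; used by the
# bootstrap inner loop, so avoids formula interfaces
metric_eval <- function(y, prs, X, idx, metric, surv = NULL) {
  p <- prs[idx]
  s <- sqrt(mean((p - mean(p))^2))
  if (!is.finite(s) || s == 0) stop("degenerate resample")
  p <- (p - mean(p)) / s
  if (metric == "auc") {
    return(auc_stat(p[y[idx] == 1], p[y[idx] == 0]))
  }
  if (metric == "beta") {
    yy <- y[idx]
    yy <- (yy - mean(yy)) / sqrt(mean((yy - mean(yy))^2))
    M <- cbind(1, p, if (!is.null(X)) X[idx, , drop = FALSE])
    return(stats::lm.fit(M, yy)$coefficients[2])
  }
  if (metric == "or") {
    M <- cbind(1, prs = p, if (!is.null(X)) X[idx, , drop = FALSE])
    fit <- suppressWarnings(stats::glm.fit(M, y[idx],
      family = binomial(),
      control = list(epsilon = 1e-8, maxit = 100)
    ))
    if (!fit$converged) stop("non-convergence")
    return(fit$coefficients[2])
  }
  if (metric == "hr") {
    M <- cbind(prs = p, if (!is.null(X)) X[idx, , drop = FALSE])
    fit <- coxph(surv[idx] ~ M, ties = "breslow")
    return(coef(fit)[[1]])
  }
  stopf("unknown metric '%s'", metric)
}

#' Paired bootstrap comparison of two PRSs on the same individuals
#'
#' Resamples individuals with replacement, using the same resample for both
#' scores (the comparison is like-for-like by construction), and computes
#' the difference of log-scale effect estimates per replicate: log-OR or
#' log-HR for disease metrics, the standardised beta for quantitative
#' traits, the AUC itself for `metric = "auc"`. The 95% CI is the
#' percentile interval of the bootstrap differences and the two-tailed p
#' is `2 * min(Pr(diff <= 0), Pr(diff >= 0))`, clipped below at
#' `2 / (n_bootstrap + 1)`.
#'
#' @param frame a `prs_frame` built with `align(..., keep_scores = TRUE)`.
#' @param score_a,score_b score column names in `frame` (a is the score of
#'   interest, b the comparator).
#' @param metric `"or"`, `"hr"`, `"beta"` or `"auc"`.
#' @param covariates covariate names for the regression metrics.
#' @param n_bootstrap number of resamples (5000 for release-grade reports).
#' @param seed RNG seed; recorded in the result.
#' @param max_failure_rate error out when more than this fraction of
#'   replicates fails (default 0.05).
#' @return A `prs_comparison` list: estimates on the comparison scale,
#'   `difference`, `ci_low`, `ci_high`, `p`, `n_bootstrap`, `seed`.
#' @export
bootstrap_compare <- function(frame, score_a, score_b, metric = c("or", "hr", "beta", "auc"),
                              covariates = c("age_at_assessment", "sex"),
                              n_bootstrap = 5000, seed = 1, max_failure_rate = 0.05) {
  metric <- match.arg(metric)
  stopifnot(score_a %in% names(frame), score_b %in% names(frame))
  keep <- !is.na(frame[[score_a]]) & !is.na(frame[[score_b]])
  fr <- frame[keep, , drop = FALSE]
  n <- nrow(fr)
  y <- if (metric == "beta") fr$value else fr$case
  cf <- covariate_frame(fr, if (metric %in% c("or", "beta")) covariates else setdiff(covariates, "age_at_assessment"))
  ok <- cf$keep
  fr <- fr[ok, , drop = FALSE]
  y <- y[ok]
  X <- if (!is.null(cf$X)) cf$X[ok, , drop = FALSE] else NULL
  n <- nrow(fr)
  surv <- NULL
  if (metric == "hr") {
    sp <- surv_pieces(fr, attr(frame, "incidence_mode") %||% "lifetime")
    fr <- fr[sp$keep, , drop = FALSE]
    if (!is.null(X)) X <- X[sp$keep, , drop = FALSE]
    n <- nrow(fr)
    surv <- if (is.null(sp$start)) Surv(sp$time, sp$event) else Surv(sp$start, sp$time, sp$event)
  }
  a <- fr[[score_a]]
  b <- fr[[score_b]]

  est_a <- metric_eval(y, a, X, seq_len(n), metric, surv)
  est_b <- metric_eval(y, b, X, seq_len(n), metric, surv)

  if (identical(a, b)) {
    return(structure(list(
      metric = metric, score_a = score_a, score_b = score_b,
      estimate_a = est_a, estimate_b = est_b, difference = 0,
      ci_low = 0, ci_high = 0, p = 1, n = n,
      n_bootstrap = n_bootstrap, n_failed = 0L, seed = seed
    ), class = "prs_comparison"))
  }

  diffs <- rep(NA_real_, n_bootstrap)
  with_substream(seed, paste0("bootstrap_compare/", score_a, "/", score_b), {
    for (r in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      diffs[r] <- tryCatch(
        metric_eval(y, a, X, idx, metric, surv) - metric_eval(y, b, X, idx, metric, surv),
        error = function(e) NA_real_
      )
    }
  })
  n_failed <- sum(is.na(diffs))
  if (n_failed > max_failure_rate * n_bootstrap) {
    stopf("metric failed in %d/%d bootstrap replicates", n_failed, n_bootstrap)
  }
  diffs <- diffs[!is.na(diffs)]
  ci <- unname(quantile(diffs, c(0.025, 0.975)))
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(1, max(p, 2 / (n_bootstrap + 1)))
  structure(list(
    metric = metric, score_a = score_a, score_b = score_b,
    estimate_a = est_a, estimate_b = est_b, difference = est_a - est_b,
    ci_low = ci[1], ci_high = ci[2], p = p, n = n,
    n_bootstrap = n_bootstrap, n_failed = n_failed, seed = seed
  ), class = "prs_comparison")
}

#' @export
print.prs_comparison <- function(x, ...) {
  cat(sprintf(
    "<prs_comparison> %s vs %s (%s): diff %.4g (95%% CI %.4g to %.4g), p = %.3g [%d bootstraps, seed %d]\n",
    x$score_a, x$score_b, x$metric, x$difference, x$ci_low, x$ci_high,
    x$p, x$n_bootstrap, x$seed
  ))
  invisible(x)
}

rel_change_scale <- function(est) {
  if (isTRUE(est$log_scale)) {
    list(value = est$log_estimate, se = est$se)
  } else {
    list(value = est$estimate, se = est$se)
  }
}

#' Relative change in performance versus a reference ancestry
#'
#' `(effect_target - effect_ref) / effect_ref` on the log scale for ratio
#' metrics (log-OR / log-HR) and on the beta scale for quantitative traits,
#' with a delta-method 95% CI treating the two strata as independent.
#' Reported in percent (a reduction is negative).
#'
#' @param target,reference `prs_effect` estimates for the same trait in the
#'   target and reference (e.g. European) ancestry groups.
#' @return A `prs_relative_change` list with `percent`, `se_percent`,
#'   `ci_low`, `ci_high` (percent scale).
#' @export
ancestry_relative_change <- function(target, reference) {
  if (isTRUE(target$gated) || isTRUE(reference$gated)) stopf("both estimates must be gated in")
  t <- rel_change_scale(target)
  r <- rel_change_scale(reference)
  if (!is.finite(r$value) || r$value <= 0) {
    stopf("reference effect must be positive on the comparison scale")
  }
  rel <- (t$value - r$value) / r$value
  se <- sqrt(t$se^2 / r$value^2 + t$value^2 * r$se^2 / r$value^4)
  structure(list(
    trait = target$stratum$trait,
    target_stratum = target$stratum$ancestry %||% NA_character_,
    reference_stratum = reference$stratum$ancestry %||% NA_character_,
    percent = 100 * rel, se_percent = 100 * se,
    ci_low = 100 * (rel - qnorm(0.975) * se),
    ci_high = 100 * (rel + qnorm(0.975) * se)
  ), class = "prs_relative_change")
}

#' Average relative performance change across traits
#'
#' Inverse-variance-weighted fixed-effect mean of per-trait relative
#' changes, with its 95% CI; reduces to the single input when only one
#' trait is available.
#'
#' @param changes list of `prs_relative_change` objects.
#' @return A `prs_relative_change` for the pooled average.
#' @export
average_relative_change <- function(changes) {
  changes <- Filter(function(ch) is.finite(ch$percent) && is.finite(ch$se_percent), changes)
  if (!length(changes)) stopf("no defined relative changes to average")
  v <- vapply(changes, function(ch) ch$percent, 0)
  w <- 1 / vapply(changes, function(ch) ch$se_percent, 0)^2
  m <- sum(w * v) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(list(
    trait = sprintf("pooled (%d traits)", length(changes)),
    target_stratum = changes[[1]]$target_stratum,
    reference_stratum = changes[[1]]$reference_stratum,
    percent = m, se_percent = se,
    ci_low = m - qnorm(0.975) * se, ci_high = m + qnorm(0.975) * se
  ), class = "prs_relative_change")
}

#' @export
print.prs_relative_change <- function(x, ...) {
  cat(sprintf(
    "<prs_relative_change> %s, %s vs %s: %+.1f%% (95%% CI %+.1f to %+.1f%%)\n",
    x$trait, x$target_stratum, x$reference_stratum, x$percent, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' Apply the minimum-case gate to effect estimates
#'
#' Estimates whose case count falls below `min_cases` ("at least
#' `min_cases` cases") are suppressed: the estimate, SE and CI are blanked
#' while counts and stratum labels are retained.
#'
#' @param estimates a `prs_effect` or list of them.
#' @param min_cases the gate (default 100).
#' @return Same shape as `estimates`, with gated entries suppressed.
#' @export
gate <- function(estimates, min_cases = 100) {
  one <- function(e) {
    if (!isTRUE(e$gated) && !is.na(e$n_cases) && e$n_cases < min_cases) {
      effect_estimate(e$metric, NA, NA, e$n_total, e$n_cases,
        stratum = e$stratum, log_scale = e$log_scale,
        gated = TRUE, gate_reason = sprintf("fewer than %d cases", min_cases)
      )
    } else {
      e
    }
  }
  if (inherits(estimates, "prs_effect")) one(estimates) else lapply(estimates, one)
}

#' Bonferroni-adjust comparison p-values (optional helper)
#'
#' The core pipeline reports nominal significance; this helper adjusts a
#' set of comparison p-values for multiple testing when requested.
#'
#' @param comparisons list of `prs_comparison` objects.
#' @return The list with an added `p_adjusted` per element.
#' @export
adjust_comparisons <- function(comparisons) {
  p <- vapply(comparisons, function(cm) cm$p, 0)
  padj <- stats::p.adjust(p, method = "bonferroni")
  Map(function(cm, pa) {
    cm$p_adjusted <- pa
    cm
  }, comparisons, padj)
}
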