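# PRS percentile bands and Kaplan-Meier cumulative incidence. Curves are on
# the age axis; cumulative incidence is one minus the product-limit survival
# estimate, with Greenwood variance and complementary log-log 95% intervals.

#' Define a PRS percentile band
#'
#' @param low,high percentiles in `[0, 100]`, `low < high`. Membership is
#'   `low < percentile rank <= high`.
#' @param label display label; default e.g. `"40-60%"`.
#' @return A `percentile_band` list.
#' @export
percentile_band <- function(low, high, label = NULL) {
  stopifnot(low >= 0, high <= 100, low < high)
  structure(list(
    low = low, high = high,
    label = label %||% sprintf("%g-%g%%", low, high)
  ), class = "percentile_band")
}

default_bands <- function() {
  list(
    percentile_band(97, 100, "top 3%"),
    percentile_band(40, 60, "40-60%"),
    percentile_band(0, 3, "bottom 3%")
  )
}

#' Assign individuals to PRS percentile bands
#'
#' Percentile rank is the "<=" empirical CDF of the score within the
#' evaluation subgroup: `100 * rank / n`, with ties broken deterministically
#' by (score, stable id order), so membership is invariant to row order and
#' to monotone transforms of the score.
#'
#' @param scores numeric score vector for the evaluation subgroup.
#' @param bands list of [percentile_band()]s (default: top 3%, 40-60%,
#'   bottom 3%).
#' @param ids optional ids used for stable tie-breaking (default: position).
#' @return Character vector of band labels aligned with `scores` (`NA` for
#'   individuals in no configured band), with the bands as an attribute.
#' @export
assign_bands <- function(scores, bands = default_bands(), ids = NULL) {
  n <- length(scores)
  if (!n) stopf("empty score vector")
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(n))
  ord <- order(scores, as.character(ids))
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  pct <- 100 * rk / n
  out <- rep(NA_character_, n)
  for (b in bands) {
    memb <- pct > b$low & pct <= b$high
    if (!any(memb)) warnf("band %s is empty at n = %d", b$label, n)
    out[memb] <- b$label
  }
  structure(out, bands = bands)
}

#' Kaplan-Meier cumulative incidence for one PRS band
#'
#' Product-limit estimate on the age axis for the selected band members.
#' `mode = "lifetime"` enters individuals at age 0 and uses all recorded
#' diagnoses; `mode = "incident"` left-truncates at age at first assessment
#' and excludes prevalent cases. Death and loss to follow-up are treated as
#' censoring. A curve whose event count does not exceed `min_cases_curve`
#' is suppressed (counts retained).
#'
#' @param frame a `prs_frame` from [align()] with a binary phenotype.
#' @param members logical vector selecting band members (default: all).
#' @param mode `"lifetime"` or `"incident"`.
#' @param min_cases_curve suppress the curve unless events exceed this
#'   number (default 40, i.e. "more than 40 cases"); `-Inf` disables.
#' @param band the [percentile_band()] the membership came from (metadata).
#' @param conf_level confidence level for the pointwise log(-log) interval.
#' @return A `prs_incidence` object: a data.frame with columns `age`,
#'   `cum_inc`, `ci_low`, `ci_high`, `n_risk`, `n_event`, or a suppressed
#'   stub when gated.
#' @export
km_curve <- function(frame, members = NULL, mode = attr(frame, "incidence_mode") %||% "lifetime",
                     min_cases_curve = 40, band = NULL, conf_level = 0.95) {
  if (is.null(members)) members <- rep(TRUE, nrow(frame))
  sub <- frame[members & !is.na(members), , drop = FALSE]
  if (!nrow(sub)) stopf("no individuals in the band")
  sp <- surv_pieces(sub, mode)
  if (any(sp$time <= 0)) stopf("nonpositive event/censoring ages")
  n_events <- sum(sp$event)
  meta <- list(
    band = band, mode = mode, n = sum(sp$keep), n_events = n_events,
    trait = attr(frame, "trait_code"), score = attr(frame, "score_name")
  )
  if (n_events <= min_cases_curve) {
    return(structure(
      data.frame(age = numeric(), cum_inc = numeric(), ci_low = numeric(),
                 ci_high = numeric(), n_risk = integer(), n_event = integer()),
      class = c("prs_incidence", "data.frame"),
      meta = meta, suppressed = TRUE,
      gate_reason = sprintf("%d events; curve requires more than %g", n_events, min_cases_curve)
    ))
  }
  ss <- if (is.null(sp$start)) Surv(sp$time, sp$event) else Surv(sp$start, sp$time, sp$event)
  fit <- survfit(ss ~ 1, conf.type = "log-log", conf.int = conf_level)
  entry_age <- if (is.null(sp$start)) 0 else min(sp$start)
  out <- data.frame(
    age = c(entry_age, fit$time),
    cum_inc = c(0, 1 - fit$surv),
    ci_low = c(0, 1 - fit$upper),
    ci_high = c(0, 1 - fit$lower),
    n_risk = c(fit$n.risk[1], fit$n.risk),
    n_event = c(0, fit$n.event)
  )
  # survfit leaves the CI NA where no event has yet occurred
  out$ci_low[is.na(out$ci_low)] <- out$cum_inc[is.na(out$ci_low)]
  out$ci_high[is.na(out$ci_high)] <- out$cum_inc[is.na(out$ci_high)]
  structure(out, class = c("prs_incidence", "data.frame"), meta = meta, suppressed = FALSE)
}

#' Evaluate a cumulative-incidence curve at an age
#'
#' Right-continuous step-function evaluation. Ages before the first grid
#' point give 0; ages beyond the last grid point return the last value with
#' an `extrapolated` flag.
#'
#' @param curve a `prs_incidence` from [km_curve()].
#' @param age age in years.
#' @return List with `estimate`, `ci_low`, `ci_high`, `extrapolated`.
#' @export
risk_at_age <- function(curve, age) {
  if (isTRUE(attr(curve, "suppressed"))) stopf("curve was suppressed: %s", attr(curve, "gate_reason"))
  i <- findInterval(age, curve$age) # right-continuous: events at `age` included
  if (i == 0) {
    return(list(estimate = 0, ci_low = 0, ci_high = 0, extrapolated = FALSE))
  }
  list(
    estimate = curve$cum_inc[i], ci_low = curve$ci_low[i], ci_high = curve$ci_high[i],
    extrapolated = age > max(curve$age)
  )
}

#' Cumulative incidence curves for each configured PRS band
#'
#' Convenience wrapper: assigns bands on the frame's standardised score and
#' computes one [km_curve()] per band.
#'
#' @inheritParams km_curve
#' @param bands list of [percentile_band()]s.
#' @return Named list of `prs_incidence` objects (one per band).
#' @export
band_curves <- function(frame, bands = default_bands(), mode = attr(frame, "incidence_mode") %||% "lifetime",
                        min_cases_curve = 40) {
  lab <- assign_bands(frame$prs, bands, ids = frame$individual_id)
  out <- list()
  for (b in bands) {
    out[[b$label]] <- km_curve(frame, lab == b$label, mode = mode,
      min_cases_curve = min_cases_curve, band = b
    )
  }
  out
}

#' @export
print.prs_incidence <- function(x, ...) {
  m <- attr(x, "meta")
  if (isTRUE(attr(x, "suppressed"))) {
    cat(sprintf(
      "<prs_incidence> %s: suppressed (%s)\n",
      m$band$label %||% "all", attr(x, "gate_reason")
    ))
  } else {
    cat(sprintf(
      "<prs_incidence> %s (%s mode): n = %d, events = %d, final incidence %.3f at age %.1f\n",
      m$band$label %||% "all", m$mode, m$n, m$n_events,
      x$cum_inc[nrow(x)], x$age[nrow(x)]
    ))
  }
  invisible(x)
}

#' Plot cumulative-incidence curves by PRS band
#'
#' Step curves with shaded pointwise confidence bands, one colour per band
#' (highest band red, median green, lowest blue by convention).
#'
#' @param x a list of `prs_incidence` objects (from [band_curves()]) or a
#'   single curve.
#' @param col colours recycled over bands.
#' @param xlim,main usual graphics parameters.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_incidence <- function(x, col = c("#d62728", "#2ca02c", "#1f77b4"),
                           xlim = NULL, main = NULL, ...) {
  if (inherits(x, "prs_incidence")) x <- list(curve = x)
  x <- Filter(function(cv) !isTRUE(attr(cv, "suppressed")), x)
  if (!length(x)) stopf("all curves suppressed")
  col <- rep_len(col, length(x))
  xmax <- max(vapply(x, function(cv) max(cv$age), 0))
  ymax <- max(vapply(x, function(cv) max(cv$ci_high), 0))
  graphics::plot(NA,
    xlim = xlim %||% c(0, xmax), ylim = c(0, ymax * 1.05),
    xlab = "Age (years)", ylab = "Cumulative incidence",
    main = main %||% (attr(x[[1]], "meta")$trait %||% ""), ...
  )
  for (i in seq_along(x)) {
    cv <- x[[i]]
    a <- c(cv$age, max(cv$age))
    graphics::polygon(
      c(rep(cv$age, each = 2)[-1], max(cv$age), rev(rep(cv$age, each = 2)[-1]), cv$age[1]),
      c(rep(cv$ci_high, each = 2)[-(2 * nrow(cv))], cv$ci_high[nrow(cv)],
        rev(rep(cv$ci_low, each = 2)[-(2 * nrow(cv))]), cv$ci_low[1]),
      col = grDevices::adjustcolor(col[i], alpha.f = 0.2), border = NA
    )
    graphics::lines(cv$age, cv$cum_inc, type = "s", col = col[i], lwd = 2)
  }
  graphics::legend("topleft",
    legend = names(x), col = col, lwd = 2, bty = "n"
  )
  invisible(x)
}
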