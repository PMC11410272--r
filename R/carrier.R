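# Rare-variant carrier risk versus PRS-band risk: carrier cumulative
# incidence, risk-matched percentile search, case-count ratios by age, and
# PRS modulation of carrier risk.

carrier_flags <- function(frame, carriers) {
  stopifnot(inherits(carriers, "carrier_table"))
  fl <- carriers$carrier[match(frame$individual_id, carriers$individual_id)]
  fl[is.na(fl)] <- 0L
  fl == 1L
}

#' Cumulative disease risk in rare-variant carriers
#'
#' Kaplan-Meier cumulative incidence among carriers, evaluated at the
#' anchor age (default 70, the usual comparison age for carrier risk).
#'
#' @param frame a `prs_frame` with a binary phenotype.
#' @param carriers a [carrier_table()].
#' @param anchor_age age at which the risk is read off (default 70).
#' @param mode incidence mode passed to [km_curve()].
#' @param filter optional logical vector (length `nrow(frame)`) applying a
#'   configured subgroup filter (e.g. statin-free) before analysis.
#' @return List with `risk`, `ci_low`, `ci_high`, `n_carriers`, `n_events`
#'   and the underlying `curve`.
#' @export
carrier_cumulative_risk <- function(frame, carriers, anchor_age = 70,
                                    mode = attr(frame, "incidence_mode") %||% "lifetime",
                                    filter = NULL) {
  is_carrier <- carrier_flags(frame, carriers)
  if (!is.null(filter)) is_carrier <- is_carrier & filter
  if (!any(is_carrier)) stopf("no carriers in the evaluation group")
  freq <- mean(is_carrier)
  if (freq >= 1) stopf("carrier frequency must be below 1")
  curve <- km_curve(frame, is_carrier, mode = mode, min_cases_curve = 0)
  if (attr(curve, "meta")$n_events < 1) stopf("no carrier cases")
  r <- risk_at_age(curve, anchor_age)
  list(
    risk = r$estimate, ci_low = r$ci_low, ci_high = r$ci_high,
    n_carriers = sum(is_carrier), n_events = attr(curve, "meta")$n_events,
    carrier_frequency = freq, anchor_age = anchor_age,
    gene_set = attr(carriers, "gene_set"), curve = curve
  )
}

top_band_members <- function(frame, q) {
  lab <- assign_bands(frame$prs, list(percentile_band(100 * (1 - q), 100, "top")),
    ids = frame$individual_id
  )
  !is.na(lab)
}

top_band_risk <- function(frame, q, anchor_age, mode) {
  curve <- km_curve(frame, top_band_members(frame, q), mode = mode, min_cases_curve = -Inf)
  r <- risk_at_age(curve, anchor_age)
  list(risk = r$estimate, ci_low = r$ci_low, ci_high = r$ci_high, curve = curve)
}

#' Find the top PRS fraction whose risk matches a target risk
#'
#' Kaplan-Meier risk at the anchor age of the top-q band is, in
#' expectation, nonincreasing in q (a larger band dilutes the high-risk
#' tail), but the realized estimate is a noisy step function of q, so the
#' search evaluates every fraction on a grid (default step 0.5 percentile)
#' and returns the grid fraction whose band risk is closest to the target,
#' smallest q on ties.
#'
#' @param frame a `prs_frame` with a binary phenotype.
#' @param target_risk the carrier risk to match, in `[0, 1]`.
#' @param anchor_age comparison age (default 70).
#' @param search_bounds `c(min, max)` top fractions searched.
#' @param grid_step grid resolution as a fraction (default 0.005 = 0.5
#'   percentile).
#' @param mode incidence mode.
#' @param filter optional logical subgroup filter applied to the frame
#'   before banding (e.g. statin-free).
#' @return A `prs_equivalence` list: `q` (matched top fraction),
#'   `band_risk` with CI, `target_risk`, `anchor_age`.
#' @export
match_percentile <- function(frame, target_risk, anchor_age = 70,
                             search_bounds = c(0.001, 0.5), grid_step = 0.005,
                             mode = attr(frame, "incidence_mode") %||% "lifetime",
                             filter = NULL) {
  stopifnot(target_risk >= 0, target_risk <= 1)
  if (!is.null(filter)) {
    frame <- frame[filter & !is.na(filter), , drop = FALSE]
  }
  grid <- seq(
    max(search_bounds[1], grid_step), search_bounds[2],
    by = grid_step
  )
  evals <- lapply(grid, function(q) top_band_risk(frame, q, anchor_age, mode))
  risks <- vapply(evals, function(e) e$risk, 0)
  if (target_risk > max(risks) || target_risk < min(risks)) {
    stopf(
      "target risk %.3f outside the achievable range [%.3f, %.3f] at age %g",
      target_risk, min(risks), max(risks), anchor_age
    )
  }
  best <- order(abs(risks - target_risk), grid)[1]
  b <- evals[[best]]
  structure(list(
    q = grid[best], band_risk = b$risk, ci_low = b$ci_low, ci_high = b$ci_high,
    target_risk = target_risk, anchor_age = anchor_age, grid_step = grid_step,
    curve = b$curve
  ), class = "prs_equivalence")
}

#' @export
print.prs_equivalence <- function(x, ...) {
  cat(sprintf(
    "<prs_equivalence> top %.1f%% of the PRS matches risk %.3f at age %g (band risk %.3f, 95%% CI %.3f-%.3f)\n",
    100 * x$q, x$target_risk, x$anchor_age, x$band_risk, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' Case counts and ratios: high-PRS band versus carriers, by age
#'
#' For each age cutoff, counts diagnosed cases with event age below the
#' cutoff in the top-q PRS band and among carriers, and their ratio. The
#' two groups may overlap; the overlap is counted in both and reported
#' together with its expected size under independence.
#'
#' @param frame a `prs_frame` with a binary phenotype.
#' @param q top PRS fraction defining the high-PRS group.
#' @param carriers a [carrier_table()].
#' @param cutoffs age cutoffs (default `c(50, 60, 70)`, i.e. cases
#'   diagnosed before 50, 60, 70).
#' @param filter optional logical subgroup filter.
#' @return A `prs_case_ratio` list with per-cutoff counts and ratios
#'   (ratio `NA` where there are no carrier cases) and overlap counts.
#' @export
case_ratio_by_age <- function(frame, q, carriers, cutoffs = c(50, 60, 70), filter = NULL) {
  if (!is.null(filter)) frame <- frame[filter & !is.na(filter), , drop = FALSE]
  in_band <- top_band_members(frame, q)
  is_carrier <- carrier_flags(frame, carriers)
  if (!any(in_band) || !any(is_carrier)) stopf("band and carrier groups must both be nonempty")
  is_case <- frame$case == 1L & !is.na(frame$event_age)
  tab <- data.frame(
    cutoff = cutoffs,
    band_cases = vapply(cutoffs, function(a) sum(is_case & in_band & frame$event_age < a), 0L),
    carrier_cases = vapply(cutoffs, function(a) sum(is_case & is_carrier & frame$event_age < a), 0L)
  )
  tab$ratio <- ifelse(tab$carrier_cases > 0, tab$band_cases / tab$carrier_cases, NA_real_)
  n <- nrow(frame)
  structure(list(
    table = tab, q = q,
    n_band = sum(in_band), n_carriers = sum(is_carrier),
    overlap = sum(in_band & is_carrier),
    expected_overlap = sum(in_band) * sum(is_carrier) / n
  ), class = "prs_case_ratio")
}

#' @export
print.prs_case_ratio <- function(x, ...) {
  cat(sprintf(
    "<prs_case_ratio> top %.1f%% band (n = %d) vs carriers (n = %d); overlap %d (expected %.1f)\n",
    100 * x$q, x$n_band, x$n_carriers, x$overlap, x$expected_overlap
  ))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' PRS modulation of carrier disease risk
#'
#' Within carriers only, cumulative-incidence curves stratified by the
#' carrier's PRS band, with bands defined on the full-cohort PRS
#' distribution (default top 10%, median 40-60%, bottom 10%).
#'
#' @param frame a `prs_frame` with a binary phenotype.
#' @param carriers a [carrier_table()].
#' @param bands list of [percentile_band()]s on the full-cohort
#'   distribution.
#' @param min_cases_curve per-band event gate (curves with no more than
#'   this many events are suppressed).
#' @param mode incidence mode.
#' @return Named list of `prs_incidence` curves, one per band; an error if
#'   every band is suppressed.
#' @export
prs_modulation_of_carriers <- function(frame, carriers,
                                       bands = list(
                                         percentile_band(90, 100, "top 10%"),
                                         percentile_band(40, 60, "40-60%"),
                                         percentile_band(0, 10, "bottom 10%")
                                       ),
                                       min_cases_curve = 10,
                                       mode = attr(frame, "incidence_mode") %||% "lifetime") {
  lab <- assign_bands(frame$prs, bands, ids = frame$individual_id)
  is_carrier <- carrier_flags(frame, carriers)
  out <- list()
  for (b in bands) {
    out[[b$label]] <- km_curve(frame, is_carrier & !is.na(lab) & lab == b$label,
      mode = mode, min_cases_curve = min_cases_curve, band = b
    )
  }
  if (all(vapply(out, function(cv) isTRUE(attr(cv, "suppressed")), TRUE))) {
    stopf("all carrier PRS bands fell below the curve gate")
  }
  out
}
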