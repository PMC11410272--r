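# Seeded synthetic-cohort generator. Emulates an ancestry-stratified biobank
# testing subgroup: standard-normal PRSs with configurable cross-trait
# correlation and per-ancestry shift/scale, proportional-hazards disease
# onset on the age scale (piecewise-constant baseline, optional linear age
# interaction on the log-hazard), rare carriers with elevated hazard,
# all-cause mortality driving both censoring and parental lifespans, and
# quantitative traits linear in PRS. All randomness flows from one root seed
# through named sub-streams, so adding a trait never perturbs another
# trait's draws.

check_baseline <- function(b) {
  stopifnot(
    is.list(b), length(b$breaks) == length(b$rates) + 1,
    !is.unsorted(b$breaks), all(b$rates >= 0)
  )
  b
}

# cumulative baseline hazard at ages t
piecewise_cumhaz <- function(baseline, t) {
  br <- baseline$breaks
  ra <- baseline$rates
  cumL <- c(0, cumsum(ra * diff(br)))
  k <- findInterval(pmin(t, br[length(br)]), br, all.inside = TRUE)
  pmin0 <- pmax(pmin(t, br[length(br)]) - br[k], 0)
  cumL[k] + ra[k] * pmin0
}

# inverse-transform sampling of event ages under a proportional-hazards
# model with piecewise-constant baseline; `entry` conditions on being
# event-free at that age. Returns Inf when no event occurs before the last
# break. With a nonzero age interaction the log-hazard multiplier is
# eta + age_slope * x * age, integrated over 1-year sub-bins.
sample_event_ages <- function(baseline, eta, entry = 0, age_slope = 0, x = NULL) {
  n <- length(eta)
  br <- baseline$breaks
  ra <- baseline$rates
  E <- stats::rexp(n)
  if (age_slope == 0) {
    cumL <- c(0, cumsum(ra * diff(br)))
    tgt <- E / exp(eta) + piecewise_cumhaz(baseline, entry)
    k <- findInterval(tgt, cumL)
    out <- rep(Inf, n)
    ok <- k <= length(ra) & ra[pmin(k, length(ra))] > 0
    out[ok] <- br[k[ok]] + (tgt[ok] - cumL[k[ok]]) / ra[k[ok]]
    return(out)
  }
  stopifnot(!is.null(x), length(x) == n)
  entry <- rep_len(entry, n)
  lo <- floor(min(entry))
  hi <- br[length(br)]
  edges <- seq(lo, hi, by = 1)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  out <- rep(Inf, n)
  acc <- numeric(n)
  base_rate <- ra[findInterval(edges[-length(edges)] + 0.5, br, all.inside = TRUE)]
  for (j in seq_len(length(edges) - 1)) {
    a0 <- edges[j]
    a1 <- edges[j + 1]
    mid <- (a0 + a1) / 2
    w <- pmax(0, a1 - pmax(a0, entry)) # portion of the bin after entry
    h <- base_rate[j] * exp(eta + age_slope * x * mid)
    inc <- h * w
    hit <- is.infinite(out) & (acc + inc >= E) & h > 0
    out[hit] <- pmax(a0, entry[hit]) + (E[hit] - acc[hit]) / h[hit]
    acc <- acc + inc
  }
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a biobank testing subgroup: ancestry sizes proportional
#' to a large European group with smaller South Asian, African and East
#' Asian groups; assessment at ages 40-69 with ~15 years of administrative
#' follow-up; a coronary-disease-like baseline hazard; rare carriers
#' (frequency 0.35%) with a hazard ratio of 3; a quantitative lipid-like
#' trait linear in PRS; all-cause mortality depending on the PRS at log-HR
#' 0.2 per SD; and parental latent scores correlated 0.5 with offspring.
#'
#' @param n_per_ancestry named integer vector of group sizes.
#' @param score_names PRS column names.
#' @param score_cor cross-score correlation matrix (must be positive
#'   semi-definite).
#' @param ancestry_shift,ancestry_scale named per-ancestry mean shift and
#'   SD scale applied to all raw scores.
#' @param diseases list of disease specs; each a list with `trait_code`,
#'   `score`, `log_hr_per_sd`, `sex_log_hr`, `age_slope` (linear age
#'   interaction on the log-hazard), `baseline` (`list(breaks, rates)`),
#'   optional `carrier` (`list(freq, log_hr)`) and optional
#'   `sex_restriction`.
#' @param quant_traits list of quantitative specs; each a list with
#'   `trait_code`, `score`, `beta_per_sd`, `noise_sd`, `sex_shift`.
#' @param assessment_age_range uniform range of age at first assessment.
#' @param followup_years administrative censoring after assessment.
#' @param mortality list: `baseline` and named `log_hr_per_sd` over scores.
#' @param parents list: `rho` (parent-offspring PRS correlation),
#'   `age_gap_mean`, `age_gap_sd` (parent minus offspring age).
#' @param treatment list for the statin-like flag: `intercept`, `slope` on
#'   a noisy risk proxy (the first score plus standard-normal noise), and
#'   `score`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_ancestry = c(EUR = 10000, SAS = 1000, AFR = 1000, EAS = 300),
                       score_names = "PRS_CAD",
                       score_cor = diag(length(score_names)),
                       ancestry_shift = NULL, ancestry_scale = NULL,
                       diseases = NULL, quant_traits = NULL,
                       assessment_age_range = c(40, 69),
                       followup_years = 15,
                       mortality = NULL, parents = list(rho = 0.5, age_gap_mean = 28, age_gap_sd = 5),
                       treatment = list(intercept = -2.5, slope = 0.8, score = score_names[1])) {
  anc <- names(n_per_ancestry)
  stopifnot(!is.null(anc), all(n_per_ancestry >= 0))
  dimnames(score_cor) <- list(score_names, score_names)
  ev <- eigen(score_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("score correlation matrix is not positive semi-definite")
  ancestry_shift <- ancestry_shift %||% setNames(rep(0, length(anc)), anc)
  ancestry_scale <- ancestry_scale %||% setNames(rep(1, length(anc)), anc)
  cad_baseline <- list(
    breaks = c(0, 40, 50, 60, 70, 80, 120),
    rates = c(2e-4, 1.5e-3, 3e-3, 6e-3, 1e-2, 1.5e-2)
  )
  mort_baseline <- list(
    breaks = c(0, 40, 50, 60, 70, 80, 90, 110),
    rates = c(5e-4, 1e-3, 3e-3, 8e-3, 2.5e-2, 8e-2, 0.25)
  )
  if (is.null(diseases)) {
    diseases <- list(list(
      trait_code = "CAD", score = score_names[1],
      log_hr_per_sd = 0.5, sex_log_hr = 0.6, age_slope = 0,
      baseline = cad_baseline,
      carrier = list(freq = 0.0035, log_hr = log(3))
    ))
  }
  for (i in seq_along(diseases)) {
    d <- diseases[[i]]
    diseases[[i]]$baseline <- check_baseline(d$baseline %||% cad_baseline)
    diseases[[i]]$sex_log_hr <- d$sex_log_hr %||% 0
    diseases[[i]]$age_slope <- d$age_slope %||% 0
    if (!is.null(d$carrier)) stopifnot(d$carrier$freq > 0, d$carrier$freq < 1)
    stopifnot(d$score %in% score_names)
  }
  if (is.null(quant_traits)) {
    quant_traits <- list(list(
      trait_code = "LIPID", score = score_names[1],
      beta_per_sd = 0.3, noise_sd = sqrt(1 - 0.3^2), sex_shift = 0.2
    ))
  }
  mortality <- mortality %||% list(
    baseline = mort_baseline,
    log_hr_per_sd = setNames(c(0.2, rep(0, length(score_names) - 1)), score_names)
  )
  mortality$baseline <- check_baseline(mortality$baseline)
  stopifnot(abs(parents$rho) < 1)
  structure(list(
    n_per_ancestry = n_per_ancestry, score_names = score_names,
    score_cor = score_cor, ancestry_shift = ancestry_shift,
    ancestry_scale = ancestry_scale, diseases = diseases,
    quant_traits = quant_traits, assessment_age_range = assessment_age_range,
    followup_years = followup_years, mortality = mortality,
    parents = parents, treatment = treatment
  ), class = "sim_config")
}

#' Simulate a full synthetic cohort
#'
#' Draws the cohort, score set, phenotypes, carrier tables, a statin-like
#' treatment flag and parental records from a [sim_config()]. Fully
#' reproducible: the same seed gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed.
#' @return List with elements `cohort` (a [cohort_table()] with parental
#'   records attached), `scores` (a [score_set()]), `phenotypes` (named
#'   list), `carriers` (named list of [carrier_table()]s, one per disease
#'   with a carrier spec), `treatment` (data.frame with a `treated` flag),
#'   and the `config` and `seed` used.
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$n_per_ancestry)
  ancestry <- rep(names(config$n_per_ancestry), config$n_per_ancestry)
  ids <- sprintf("S%06d", seq_len(n))

  sex <- with_substream(seed, "sex", {
    ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
  })
  assess <- with_substream(seed, "assessment", {
    runif(n, config$assessment_age_range[1], config$assessment_age_range[2])
  })

  k <- length(config$score_names)
  X <- with_substream(seed, "prs", {
    Z <- matrix(rnorm(n * k), n, k)
    L <- chol(config$score_cor + diag(1e-10, k))
    Z %*% L
  })
  colnames(X) <- config$score_names
  raw <- X
  for (g in names(config$n_per_ancestry)) {
    idx <- ancestry == g
    raw[idx, ] <- X[idx, ] * config$ancestry_scale[[g]] + config$ancestry_shift[[g]]
  }

  # all-cause mortality: death after assessment; administrative censoring
  eta_mort <- drop(X %*% config$mortality$log_hr_per_sd[config$score_names])
  death_age <- with_substream(seed, "mortality", {
    sample_event_ages(config$mortality$baseline, eta_mort, entry = assess)
  })
  admin <- assess + config$followup_years
  censor_age <- pmin(admin, death_age)
  death_obs <- ifelse(death_age <= admin, death_age, NA_real_)

  cohort_df <- data.frame(
    individual_id = ids, sex = sex, age_at_assessment = assess,
    ancestry = ancestry, censor_age = censor_age, death_age = death_obs,
    stringsAsFactors = FALSE
  )

  phenotypes <- list()
  carriers <- list()
  for (d in config$diseases) {
    xs <- X[, d$score] # latent standard-normal scale drives the hazard
    carrier <- rep(0L, n)
    eta <- d$log_hr_per_sd * xs + d$sex_log_hr * (sex == "male")
    if (!is.null(d$carrier)) {
      carrier <- with_substream(seed, paste0("carrier/", d$trait_code), {
        stats::rbinom(n, 1, d$carrier$freq)
      })
      eta <- eta + d$carrier$log_hr * carrier
      carriers[[d$trait_code]] <- carrier_table(
        data.frame(individual_id = ids, carrier = carrier),
        gene_set = paste0(d$trait_code, "_genes")
      )
    }
    onset <- with_substream(seed, paste0("disease/", d$trait_code), {
      sample_event_ages(d$baseline, eta, entry = 0, age_slope = d$age_slope, x = xs)
    })
    case <- as.integer(onset <= censor_age)
    if (!is.null(d$sex_restriction)) case[sex != d$sex_restriction] <- 0L
    phenotypes[[d$trait_code]] <- binary_phenotype(
      data.frame(
        individual_id = ids, case = case,
        event_age = ifelse(case == 1L, onset, NA_real_)
      ),
      trait_code = d$trait_code, sex_restriction = d$sex_restriction
    )
  }
  for (q in config$quant_traits) {
    value <- with_substream(seed, paste0("quant/", q$trait_code), {
      q$beta_per_sd * X[, q$score] + q$sex_shift * (sex == "male") +
        rnorm(n, 0, q$noise_sd)
    })
    phenotypes[[q$trait_code]] <- quant_phenotype(
      data.frame(individual_id = ids, value = value),
      trait_code = q$trait_code
    )
  }

  treatment <- with_substream(seed, "treatment", {
    proxy <- X[, config$treatment$score] + rnorm(n)
    data.frame(
      individual_id = ids,
      treated = stats::rbinom(n, 1, plogis(config$treatment$intercept + config$treatment$slope * proxy)) == 1
    )
  })

  parents <- simulate_parents(config, X, seed, assessment_age = assess, ids = ids)
  cohort <- cohort_table(cohort_df, parents = parents, incidence_mode = "lifetime")
  scores <- score_set(
    cbind(data.frame(individual_id = ids, stringsAsFactors = FALSE), as.data.frame(raw)),
    meta = data.frame(
      score_name = config$score_names,
      trait_code = sub("^PRS_", "", config$score_names),
      source = "enhanced", stringsAsFactors = FALSE
    )
  )
  list(
    cohort = cohort, scores = scores, phenotypes = phenotypes,
    carriers = carriers, treatment = treatment, config = config, seed = seed
  )
}

#' Simulate parental lifespan records
#'
#' Each participant contributes two parents. A parent's latent score is
#' `rho * offspring + sqrt(1 - rho^2) * noise` per score (default
#' `rho = 0.5`, the expected parent-offspring correlation of an additive
#' genetic score), and the parent's death age is drawn from the mortality
#' hazard with the parent's own latent score effect. Parents are observed
#' up to an age offset from the offspring's assessment age
#' (`age_gap_mean` years older on average).
#'
#' @param config a [sim_config()].
#' @param offspring_scores matrix of latent (unit-SD) offspring scores,
#'   columns named as in `config$score_names`.
#' @param seed root seed (the parental sub-stream is derived from it).
#' @param assessment_age offspring assessment ages.
#' @param ids offspring ids.
#' @return data.frame with `individual_id`, `parent_sex`, `parent_age`,
#'   `parent_dead` (one row per parent).
#' @export
simulate_parents <- function(config, offspring_scores, seed, assessment_age, ids) {
  rho <- config$parents$rho
  if (abs(rho) >= 1) stopf("parent-offspring correlation must be inside (-1, 1)")
  n <- nrow(offspring_scores)
  k <- ncol(offspring_scores)
  with_substream(seed, "parents", {
    out <- vector("list", 2)
    for (p in 1:2) {
      latent <- rho * offspring_scores + sqrt(1 - rho^2) * matrix(rnorm(n * k), n, k)
      eta <- drop(latent %*% config$mortality$log_hr_per_sd[config$score_names])
      death <- sample_event_ages(config$mortality$baseline, eta)
      current <- assessment_age + rnorm(n, config$parents$age_gap_mean, config$parents$age_gap_sd)
      dead <- death <= current
      out[[p]] <- data.frame(
        individual_id = ids,
        parent_sex = if (p == 1) "female" else "male",
        parent_age = ifelse(dead, death, current),
        parent_dead = as.integer(dead),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Closed-form expected cumulative risk under the generative model
#'
#' `1 - E[exp(-HR(x) * L0(age))]` over the standard-normal PRS distribution
#' (optionally truncated to a percentile band), by adaptive quadrature.
#' Serves as the analytic oracle for the incidence and carrier-equivalence
#' analyses on simulated cohorts.
#'
#' @param config a [sim_config()].
#' @param trait_code which configured disease.
#' @param age age at which the risk is evaluated.
#' @param band optional percentile band `c(low, high)` (in percent) of the
#'   PRS distribution.
#' @param sex `"female"`, `"male"` or `NULL` (average over both).
#' @param carrier evaluate for carriers (`TRUE`) or non-carriers.
#' @return Expected cumulative risk in `[0, 1]`.
#' @export
expected_cumulative_risk <- function(config, trait_code, age, band = NULL,
                                     sex = NULL, carrier = FALSE) {
  d <- NULL
  for (dd in config$diseases) if (dd$trait_code == trait_code) d <- dd
  if (is.null(d)) stopf("no configured disease '%s'", trait_code)
  if (d$age_slope != 0) stopf("closed form implemented for age-constant effects only")
  L0 <- piecewise_cumhaz(d$baseline, age)
  if (L0 == 0) return(0)
  lo <- if (is.null(band)) -Inf else qnorm(band[1] / 100)
  hi <- if (is.null(band)) Inf else qnorm(band[2] / 100)
  mass <- pnorm(hi) - pnorm(lo)
  eta0 <- (if (carrier && !is.null(d$carrier)) d$carrier$log_hr else 0)
  one_sex <- function(s) {
    es <- eta0 + d$sex_log_hr * (s == "male")
    f <- function(x) (1 - exp(-exp(d$log_hr_per_sd * x + es) * L0)) * stats::dnorm(x)
    stats::integrate(f, lo, hi, rel.tol = 1e-9)$value / mass
  }
  if (is.null(sex)) (one_sex("female") + one_sex("male")) / 2 else one_sex(sex)
}
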