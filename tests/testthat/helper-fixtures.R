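# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except round-trip temporaries.

# minimal analysis frame, bypassing align(), for metric-level micro-tests
make_frame <- function(prs, case = NULL, event_age = NULL, value = NULL,
                       sex = NULL, age = NULL, censor_age = NULL,
                       mode = "lifetime", trait = "T") {
  n <- length(prs)
  df <- data.frame(
    individual_id = sprintf("I%04d", seq_len(n)),
    sex = sex %||% rep("female", n),
    age_at_assessment = age %||% rep(50, n),
    ancestry = "EUR",
    censor_age = censor_age %||% rep(80, n),
    death_age = NA_real_,
    prs = prs
  )
  if (!is.null(case)) {
    df$case <- as.integer(case)
    df$event_age <- if (is.null(event_age)) ifelse(df$case == 1, 60, NA) else event_age
  }
  if (!is.null(value)) df$value <- value
  structure(df,
    class = c("prs_frame", "data.frame"),
    trait_code = trait, score_name = "PRS",
    trait_type = if (is.null(value)) "binary" else "quantitative",
    incidence_mode = mode
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small three-row cohort files for the reader tests
write_cohort_file <- function(path, ids = c("A1", "A2", "A3"),
                              assess = c(45, 50, 55), censor = c(60, 65, 70)) {
  df <- data.frame(
    individual_id = ids, sex = c("female", "male", "female"),
    age_at_assessment = assess, ancestry = c("EUR", "EUR", "SAS"),
    censor_age = censor, death_age = c(NA, NA, 68)
  )
  prsbench::write_tsv_dialect(df, path)
  df
}

# cohort-level fixture: simulated study subgroup reused by slower tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_per_ancestry = c(EUR = 6000, SAS = 1500))
      cache <<- simulate_cohort(cfg, seed = 101)
    }
    cache
  }
})

eur_cohort <- function(sim) {
  co <- as.data.frame(sim$cohort)
  out <- sim$cohort[co$ancestry == "EUR", ]
  class(out) <- class(sim$cohort)
  attr(out, "incidence_mode") <- attr(sim$cohort, "incidence_mode")
  attr(out, "parents") <- attr(sim$cohort, "parents")
  out
}
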