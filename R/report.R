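# Orchestration: run the standardised evaluation for one or more PRSs and
# emit the report (JSON + tab-separated summaries + optional plots).

#' Analysis configuration for the standardised evaluation
#'
#' @param bands percentile bands for incidence curves (default top 3%,
#'   median 40-60%, bottom 3%).
#' @param min_cases_metric effect metrics require at least this many cases
#'   (default 100).
#' @param min_cases_curve incidence curves require more than this many
#'   events (default 40).
#' @param n_bootstrap resamples for score-vs-score comparisons (default
#'   5000).
#' @param seed root seed for every stochastic step.
#' @param incidence_mode `"lifetime"` or `"incident"`.
#' @param ancestries ancestry labels to report (default: all in the cohort
#'   except `"other"`/`"unclassified"`).
#' @param reference_ancestry reference group for relative performance
#'   change (default `"EUR"`).
#' @param anchor_age anchor age for carrier-equivalence analyses.
#' @param run_comparisons,run_sex_strata,run_multivariate switches for the
#'   optional report blocks.
#' @return An `analysis_config` list.
#' @export
prs_config <- function(bands = default_bands(), min_cases_metric = 100,
                       min_cases_curve = 40, n_bootstrap = 5000, seed = 1,
                       incidence_mode = c("lifetime", "incident"),
                       ancestries = NULL, reference_ancestry = "EUR",
                       anchor_age = 70, run_comparisons = TRUE,
                       run_sex_strata = TRUE, run_multivariate = TRUE) {
  for (b in bands) stopifnot(inherits(b, "percentile_band"))
  lows <- vapply(bands, `[[`, 0, "low")
  his <- vapply(bands, `[[`, 0, "high")
  ord <- order(lows)
  if (any(his[ord][-length(bands)] > lows[ord][-1])) stopf("percentile bands overlap")
  stopifnot(n_bootstrap >= 1, min_cases_metric >= 0)
  structure(list(
    bands = bands, min_cases_metric = min_cases_metric,
    min_cases_curve = min_cases_curve, n_bootstrap = n_bootstrap,
    seed = seed, incidence_mode = match.arg(incidence_mode),
    ancestries = ancestries, reference_ancestry = reference_ancestry,
    anchor_age = anchor_age, run_comparisons = run_comparisons,
    run_sex_strata = run_sex_strata, run_multivariate = run_multivariate
  ), class = "analysis_config")
}

#' Read an analysis configuration from a key-value (YAML) file
#'
#' @param path YAML file; keys match the arguments of [prs_config()], with
#'   `bands` given as a list of `[low, high]` pairs.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  kv <- yaml::read_yaml(path)
  if (!is.null(kv$bands)) {
    kv$bands <- lapply(kv$bands, function(b) percentile_band(b[[1]], b[[2]]))
  }
  do.call(prs_config, kv)
}

effect_to_list <- function(e) {
  e$stratum <- lapply(e$stratum, function(v) if (is.null(v)) NA else v)
  unclass(e)
}

capture_block <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the standardised evaluation pipeline
#'
#' Executes, per trait, score and ancestry group: score distribution
#' summaries, covariate-adjusted per-SD effect metrics and AUC (gated at
#' `min_cases_metric` cases), percentile-band cumulative-incidence curves
#' (gated at more than `min_cases_curve` events), relative ancestry
#' performance change against the reference group with cross-trait pooling,
#' paired-bootstrap comparisons between sources for the same trait,
#' sex-stratified effects with difference tests, carrier-equivalence
#' analyses where carrier tables are supplied, and the multivariate block
#' (PRS correlations, clustering order, mortality models when parental
#' records exist). Block-level failures are captured as error entries
#' rather than aborting. Deterministic given the config seed.
#'
#' @param cohort a [cohort_table()].
#' @param scores a [score_set()].
#' @param phenotypes named list of [binary_phenotype()] /
#'   [quant_phenotype()] objects.
#' @param carriers optional named list of [carrier_table()]s keyed by trait
#'   code.
#' @param config an [prs_config()].
#' @return A `prs_report` list with blocks `distribution`, `traits`,
#'   `relative_change`, `comparisons`, `sex_strata`, `carrier`,
#'   `multivariate` and `provenance`.
#' @export
run_evaluation <- function(cohort, scores, phenotypes, carriers = NULL,
                           config = prs_config()) {
  stopifnot(inherits(config, "analysis_config"))
  meta <- attr(scores, "meta")
  co <- as.data.frame(cohort)
  ancestries <- config$ancestries %||%
    setdiff(sort(unique(co$ancestry)), c("other", "unclassified"))

  report <- list()
  report$distribution <- capture_block(distribution_summary(scores, cohort))

  traits <- list()
  rel_changes <- list()
  for (trait in names(phenotypes)) {
    pheno <- phenotypes[[trait]]
    is_binary <- inherits(pheno, "binary_phenotype")
    score_cols <- meta$score_name[meta$trait_code == trait]
    if (!length(score_cols)) score_cols <- setdiff(names(scores), "individual_id")[1]
    trait_block <- list()
    for (sn in score_cols) {
      src <- meta$source[match(sn, meta$score_name)]
      per_anc <- list()
      for (anc in ancestries) {
        per_anc[[anc]] <- capture_block({
          sub_cohort <- cohort[co$ancestry == anc, , drop = FALSE]
          attr(sub_cohort, "incidence_mode") <- config$incidence_mode
          class(sub_cohort) <- class(cohort)
          frame <- align(sub_cohort, scores, pheno, score_name = sn)
          blk <- list(n = nrow(frame), dropped = as.list(attr(frame, "dropped")))
          stratum <- list(ancestry = anc, source = src)
          if (is_binary) {
            blk$or_per_sd <- effect_to_list(capture_or(
              or_per_sd(frame, min_cases = config$min_cases_metric, stratum = stratum)
            ))
            blk$auc <- effect_to_list(capture_or(
              auc_prs(frame, min_cases = config$min_cases_metric, stratum = stratum)
            ))
            blk$curves <- lapply(
              band_curves(frame,
                bands = config$bands, mode = config$incidence_mode,
                min_cases_curve = config$min_cases_curve
              ),
              curve_to_list
            )
          } else {
            blk$beta_per_sd <- effect_to_list(capture_or(
              beta_per_sd(frame, stratum = stratum)
            ))
          }
          blk
        })
      }
      trait_block[[sn]] <- per_anc

      # relative ancestry change vs the reference group, for the
      # first-listed (primary) score of each trait only
      ref <- per_anc[[config$reference_ancestry]]
      key <- if (is_binary) "or_per_sd" else "beta_per_sd"
      if (sn == score_cols[1] && !is.null(ref) && is.null(ref$error) && !isTRUE(ref[[key]]$gated)) {
        for (anc in setdiff(ancestries, config$reference_ancestry)) {
          tgt <- per_anc[[anc]]
          if (is.null(tgt) || !is.null(tgt$error) || isTRUE(tgt[[key]]$gated)) next
          rc <- capture_block(ancestry_relative_change(
            relist_effect(tgt[[key]]), relist_effect(ref[[key]])
          ))
          if (is.null(rc$error)) {
            rel_changes[[anc]] <- c(rel_changes[[anc]] %||% list(), list(rc))
          }
        }
      }
    }
    traits[[trait]] <- trait_block
  }
  report$traits <- traits

  report$relative_change <- lapply(rel_changes, function(lst) {
    list(
      per_trait = lapply(lst, unclass),
      pooled = capture_block(unclass(average_relative_change(lst)))
    )
  })

  report$comparisons <- if (config$run_comparisons) {
    capture_block(run_comparisons(cohort, scores, phenotypes, config, ancestries))
  } else {
    NULL
  }

  report$sex_strata <- if (config$run_sex_strata) {
    capture_block(run_sex_strata(cohort, scores, phenotypes, config, ancestries))
  } else {
    NULL
  }

  report$carrier <- if (!is.null(carriers)) {
    capture_block(run_carrier_block(cohort, scores, phenotypes, carriers, config))
  } else {
    NULL
  }

  report$multivariate <- if (config$run_multivariate &&
    length(setdiff(names(scores), "individual_id")) >= 2) {
    capture_block({
      cm <- prs_correlation_matrix(scores)
      list(
        correlation = unclass(cm)[, , drop = FALSE],
        cluster_order = if (!any(is.na(cm))) cluster_order(cm) else NULL
      )
    })
  } else {
    NULL
  }

  cfg_public <- config
  cfg_public$bands <- lapply(config$bands, unclass)
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("prsbench")),
    seed = config$seed,
    config = unclass(cfg_public),
    config_hash = content_hash(unclass(cfg_public)),
    incidence_mode = config$incidence_mode,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(report, class = "prs_report")
}

# wrap metric gating errors (too few cases/controls etc.) as gated entries
capture_or <- function(expr) {
  tryCatch(expr, error = function(e) {
    effect_estimate("unavailable", NA, NA, 0L, 0L,
      gated = TRUE, gate_reason = conditionMessage(e), log_scale = FALSE
    )
  })
}

relist_effect <- function(lst) structure(lst, class = "prs_effect")

curve_to_list <- function(cv) {
  m <- attr(cv, "meta")
  list(
    band = m$band$label %||% "all", n = m$n, n_events = m$n_events,
    suppressed = isTRUE(attr(cv, "suppressed")),
    gate_reason = attr(cv, "gate_reason"),
    grid = if (isTRUE(attr(cv, "suppressed"))) NULL else as.data.frame(cv)
  )
}

run_comparisons <- function(cohort, scores, phenotypes, config, ancestries) {
  meta <- attr(scores, "meta")
  out <- list()
  co <- as.data.frame(cohort)
  for (trait in names(phenotypes)) {
    sc <- meta$score_name[meta$trait_code == trait]
    if (length(sc) < 2) next
    pheno <- phenotypes[[trait]]
    is_binary <- inherits(pheno, "binary_phenotype")
    anc <- intersect(config$reference_ancestry, ancestries)
    if (!length(anc)) anc <- ancestries[1]
    sub_cohort <- cohort[co$ancestry == anc, , drop = FALSE]
    class(sub_cohort) <- class(cohort)
    frame <- align(sub_cohort, scores, pheno, score_name = sc[1], keep_scores = TRUE)
    # compare the first-listed source against each other source
    for (other in sc[-1]) {
      out[[paste(trait, sc[1], "vs", other)]] <- capture_block(unclass(
        bootstrap_compare(frame, sc[1], other,
          metric = if (is_binary) "or" else "beta",
          n_bootstrap = config$n_bootstrap,
          seed = substream_seed(config$seed, paste0("compare/", trait, "/", other))
        )
      ))
    }
  }
  out
}

run_sex_strata <- function(cohort, scores, phenotypes, config, ancestries) {
  out <- list()
  co <- as.data.frame(cohort)
  anc <- intersect(config$reference_ancestry, ancestries)
  if (!length(anc)) anc <- ancestries[1]
  sub_cohort <- cohort[co$ancestry == anc, , drop = FALSE]
  class(sub_cohort) <- class(cohort)
  for (trait in names(phenotypes)) {
    pheno <- phenotypes[[trait]]
    is_binary <- inherits(pheno, "binary_phenotype")
    restricted <- attr(pheno, "sex_restriction")
    blk <- capture_block({
      frame <- align(sub_cohort, scores, pheno)
      metric <- if (is_binary) "or" else "beta"
      strata <- list()
      sexes <- if (is.null(restricted)) c("all", "female", "male") else restricted
      for (sx in sexes) {
        strata[[sx]] <- effect_to_list(capture_or(sex_stratified_effect(
          frame, sx, metric,
          min_cases = if (is_binary) config$min_cases_metric else 0
        )))
      }
      if (is.null(restricted) &&
        !isTRUE(strata$female$gated) && !isTRUE(strata$male$gated) &&
        is.null(strata$female$error) && is.null(strata$male$error)) {
        strata$difference <- capture_block(sex_difference_test(
          relist_effect(strata$female), relist_effect(strata$male)
        ))
      }
      strata
    })
    out[[trait]] <- blk
  }
  out
}

run_carrier_block <- function(cohort, scores, phenotypes, carriers, config) {
  out <- list()
  co <- as.data.frame(cohort)
  anc <- config$reference_ancestry
  if (!(anc %in% co$ancestry)) anc <- sort(unique(co$ancestry))[1]
  sub_cohort <- cohort[co$ancestry == anc, , drop = FALSE]
  class(sub_cohort) <- class(cohort)
  for (trait in names(carriers)) {
    pheno <- phenotypes[[trait]]
    if (is.null(pheno) || !inherits(pheno, "binary_phenotype")) next
    out[[trait]] <- capture_block({
      frame <- align(sub_cohort, scores, pheno)
      cr <- carrier_cumulative_risk(frame, carriers[[trait]], anchor_age = config$anchor_age)
      mp <- capture_block(unclass(match_percentile(
        frame, cr$risk,
        anchor_age = config$anchor_age
      )))
      mp$curve <- NULL
      ratios <- if (!is.null(mp$error)) {
        list(error = mp$error)
      } else {
        unclass(case_ratio_by_age(frame, mp$q, carriers[[trait]]))
      }
      list(
        gene_set = cr$gene_set, anchor_age = config$anchor_age,
        carrier_risk = cr[c("risk", "ci_low", "ci_high", "n_carriers", "n_events", "carrier_frequency")],
        matched = mp, case_ratios = ratios
      )
    })
  }
  out
}

#' Flatten a report's effect estimates into a summary table
#'
#' One row per (trait, score, ancestry, metric) mirroring release-style
#' performance tables.
#'
#' @param report a `prs_report`.
#' @return data.frame with columns `trait`, `score`, `ancestry`, `metric`,
#'   `estimate`, `ci_low`, `ci_high`, `n`, `cases`, `gated`.
#' @export
effects_table <- function(report) {
  rows <- list()
  for (trait in names(report$traits)) {
    for (sn in names(report$traits[[trait]])) {
      for (anc in names(report$traits[[trait]][[sn]])) {
        blk <- report$traits[[trait]][[sn]][[anc]]
        if (!is.null(blk$error)) next
        for (metric in intersect(c("or_per_sd", "auc", "beta_per_sd"), names(blk))) {
          e <- blk[[metric]]
          rows[[length(rows) + 1L]] <- data.frame(
            trait = trait, score = sn, ancestry = anc, metric = metric,
            estimate = e$estimate %||% NA_real_, ci_low = e$ci_low %||% NA_real_,
            ci_high = e$ci_high %||% NA_real_, n = e$n_total %||% NA_integer_,
            cases = e$n_cases %||% NA_integer_, gated = isTRUE(e$gated),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      trait = character(), score = character(), ancestry = character(),
      metric = character(), estimate = numeric(), ci_low = numeric(),
      ci_high = numeric(), n = integer(), cases = integer(), gated = logical()
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structurally validate a report against the shipped schema
#'
#' Checks the report against the versioned structural schema in
#' `inst/schema/report-schema.json` (required blocks and required
#' provenance fields). This is a lightweight structural check, not a full
#' JSON-Schema validation.
#'
#' @param report a `prs_report` or a list parsed from report JSON.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
    package = "prsbench", mustWork = TRUE
  ))
  for (f in unlist(schema$required)) {
    if (is.null(report[[f]])) stopf("report is missing required block '%s'", f)
  }
  for (f in unlist(schema$provenance_required)) {
    if (is.null(report$provenance[[f]])) stopf("report provenance is missing '%s'", f)
  }
  invisible(TRUE)
}

#' Render a report to files
#'
#' @param report a `prs_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `"json"` (schema-validated full report),
#'   `"tsv"` (effects summary + per-band curve grids) and `"plots"`
#'   (cumulative-incidence figures, one page per trait/score/ancestry).
#' @param strip_timestamp drop the provenance timestamp so that identical
#'   runs produce byte-identical JSON.
#' @return Character vector of the files written, invisibly.
#' @export
render_summary <- function(report, dir, formats = c("json", "tsv"),
                           strip_timestamp = FALSE) {
  formats <- match.arg(formats, c("json", "tsv", "plots"), several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if ("json" %in% formats) {
    validate_report(report)
    rep2 <- report
    if (strip_timestamp) rep2$provenance$timestamp <- NULL
    path <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(rep2), path,
      auto_unbox = TRUE, digits = 12,
      na = "null", pretty = TRUE, force = TRUE
    )
    written <- c(written, path)
  }
  if ("tsv" %in% formats) {
    path <- file.path(dir, "effects.tsv")
    write_tsv_dialect(effects_table(report), path)
    written <- c(written, path)
    curves <- curve_rows(report)
    if (nrow(curves)) {
      cpath <- file.path(dir, "curves.tsv")
      write_tsv_dialect(curves, cpath)
      written <- c(written, cpath)
    }
  }
  if ("plots" %in% formats) {
    path <- file.path(dir, "incidence.pdf")
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (trait in names(report$traits)) {
      for (sn in names(report$traits[[trait]])) {
        for (anc in names(report$traits[[trait]][[sn]])) {
          blk <- report$traits[[trait]][[sn]][[anc]]
          if (!is.null(blk$error) || is.null(blk$curves)) next
          curves <- Filter(function(cl) !isTRUE(cl$suppressed), blk$curves)
          if (!length(curves)) next
          lst <- lapply(curves, function(cl) {
            structure(cl$grid,
              class = c("prs_incidence", "data.frame"),
              meta = list(band = list(label = cl$band), trait = trait),
              suppressed = FALSE
            )
          })
          plot_incidence(lst, main = sprintf("%s / %s / %s", trait, sn, anc))
        }
      }
    }
    written <- c(written, path)
  }
  invisible(written)
}

curve_rows <- function(report) {
  rows <- list()
  for (trait in names(report$traits)) {
    for (sn in names(report$traits[[trait]])) {
      for (anc in names(report$traits[[trait]][[sn]])) {
        blk <- report$traits[[trait]][[sn]][[anc]]
        if (!is.null(blk$error) || is.null(blk$curves)) next
        for (cl in blk$curves) {
          if (isTRUE(cl$suppressed) || is.null(cl$grid)) next
          g <- cl$grid
          g$trait <- trait
          g$score <- sn
          g$ancestry <- anc
          g$band <- cl$band
          rows[[length(rows) + 1L]] <- g
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.prs_report <- function(x, ...) {
  cat(sprintf(
    "<prs_report> %d trait(s); seed %s; config %s\n",
    length(x$traits), x$provenance$seed, x$provenance$config_hash
  ))
  tab <- effects_table(x)
  if (nrow(tab)) print(head(tab, 20), row.names = FALSE, digits = 4)
  invisible(x)
}
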