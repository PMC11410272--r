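# Cohort, score, phenotype and carrier tables: constructors, tab-separated
# readers/writers, alignment and validation. All tables are plain data.frames
# with a light S3 class and attributes carrying metadata, in the style of the
# survival package rather than a heavyweight container.

SEX_LEVELS <- c("female", "male")

#' Construct and validate a cohort table
#'
#' One row per individual with the covariates every downstream analysis
#' joins against: sex, age at first assessment, genetic-ancestry label and
#' follow-up (censoring) age, plus optional death age and parental lifespan
#' records.
#'
#' @param df data.frame with columns `individual_id`, `sex`
#'   (`"female"`/`"male"`), `age_at_assessment`, `ancestry`, `censor_age`,
#'   and optionally `death_age`.
#' @param parents optional data.frame of parental observations with columns
#'   `individual_id`, `parent_sex`, `parent_age` (age at death or at last
#'   observation) and `parent_dead` (0/1); each parent is one row.
#' @param incidence_mode `"lifetime"` (entry at age 0, retrospective
#'   diagnoses included) or `"incident"` (left truncation at assessment age).
#'   In incident mode rows with `censor_age < age_at_assessment` are invalid.
#' @return A `cohort_table` (data.frame). Rows failing row-level invariants
#'   are dropped and recorded in `attr(, "rejected")` with a reason each.
#'   Duplicate ids are an error.
#' @export
cohort_table <- function(df, parents = NULL, incidence_mode = c("lifetime", "incident")) {
  incidence_mode <- match.arg(incidence_mode)
  req <- c("individual_id", "sex", "age_at_assessment", "ancestry", "censor_age")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stopf("cohort table is missing required column(s): %s", paste(miss, collapse = ", "))
  }
  df$individual_id <- as.character(df$individual_id)
  dup <- unique(df$individual_id[duplicated(df$individual_id)])
  if (length(dup)) {
    stopf("duplicate individual_id value(s): %s", paste(head(dup, 10), collapse = ", "))
  }
  df$sex <- tolower(as.character(df$sex))
  df$sex[!(df$sex %in% SEX_LEVELS)] <- NA_character_
  df$age_at_assessment <- as.numeric(df$age_at_assessment)
  df$censor_age <- as.numeric(df$censor_age)
  if (!("death_age" %in% names(df))) df$death_age <- NA_real_
  df$death_age <- as.numeric(df$death_age)
  df$ancestry <- as.character(df$ancestry)

  reason <- rep(NA_character_, nrow(df))
  bad_age <- !is.finite(df$age_at_assessment) | df$age_at_assessment <= 0
  reason[bad_age] <- "age_at_assessment missing or nonpositive"
  bad_cens <- is.na(reason) & !is.finite(df$censor_age)
  reason[bad_cens] <- "censor_age missing"
  if (incidence_mode == "incident") {
    bad_fu <- is.na(reason) & df$censor_age < df$age_at_assessment
    reason[bad_fu] <- "censor_age before age_at_assessment in incident mode"
  }
  bad_death <- is.na(reason) & !is.na(df$death_age) & df$death_age > df$censor_age
  reason[bad_death] <- "death_age after censor_age"

  rejected <- data.frame(
    individual_id = df$individual_id[!is.na(reason)],
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(parents)) {
    preq <- c("individual_id", "parent_sex", "parent_age", "parent_dead")
    pmiss <- setdiff(preq, names(parents))
    if (length(pmiss)) {
      stopf("parent table is missing column(s): %s", paste(pmiss, collapse = ", "))
    }
    parents$individual_id <- as.character(parents$individual_id)
    parents <- parents[parents$individual_id %in% out$individual_id, , drop = FALSE]
    rownames(parents) <- NULL
  }
  structure(out,
    class = c("cohort_table", "data.frame"),
    parents = parents,
    incidence_mode = incidence_mode,
    rejected = rejected
  )
}

#' Construct a score set
#'
#' @param df data.frame with `individual_id` plus one numeric column per
#'   named PRS.
#' @param meta optional data.frame with columns `score_name`, `trait_code`,
#'   `source` (`"enhanced"`, `"standard"` or `"comparator"`) describing each
#'   score column.
#' @return A `score_set` (data.frame) with score metadata attached.
#' @export
score_set <- function(df, meta = NULL) {
  if (!("individual_id" %in% names(df))) stopf("score table needs an individual_id column")
  df$individual_id <- as.character(df$individual_id)
  dup <- unique(df$individual_id[duplicated(df$individual_id)])
  if (length(dup)) stopf("duplicate individual_id value(s) in scores: %s", paste(head(dup, 10), collapse = ", "))
  score_cols <- setdiff(names(df), "individual_id")
  if (!length(score_cols)) stopf("score table has no score columns")
  for (s in score_cols) df[[s]] <- as.numeric(df[[s]])
  if (is.null(meta)) {
    meta <- data.frame(
      score_name = score_cols, trait_code = score_cols,
      source = "enhanced", stringsAsFactors = FALSE
    )
  } else {
    miss <- setdiff(score_cols, meta$score_name)
    if (length(miss)) stopf("score metadata missing for: %s", paste(miss, collapse = ", "))
  }
  structure(df, class = c("score_set", "data.frame"), meta = meta)
}

#' Construct a binary (disease) phenotype
#'
#' @param df data.frame with `individual_id`, `case` (0/1) and `event_age`
#'   (years; required for cases, ignored for controls).
#' @param trait_code short trait label (e.g. `"CAD"`).
#' @param sex_restriction optional `"female"` or `"male"` for sex-specific
#'   diseases; the other sex is excluded at alignment.
#' @param age_window optional `c(min, max)` age range used when displaying
#'   incidence curves (e.g. `c(0, 20)` for type 1 diabetes).
#' @return A `binary_phenotype` (data.frame). Cases without an event age are
#'   rejected (recorded in `attr(, "rejected")`), not imputed.
#' @export
binary_phenotype <- function(df, trait_code, sex_restriction = NULL, age_window = NULL) {
  req <- c("individual_id", "case")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("binary phenotype missing column(s): %s", paste(miss, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$case <- as.integer(df$case)
  if (!("event_age" %in% names(df))) df$event_age <- NA_real_
  df$event_age <- as.numeric(df$event_age)
  if (!all(df$case %in% c(0L, 1L))) stopf("case flag must be 0/1")
  if (!is.null(sex_restriction)) sex_restriction <- match.arg(sex_restriction, SEX_LEVELS)
  bad <- (df$case == 1L & is.na(df$event_age)) | (df$case == 1L & !is.na(df$event_age) & df$event_age <= 0)
  rejected <- data.frame(
    individual_id = df$individual_id[bad],
    reason = rep("case without a valid event_age", sum(bad)), stringsAsFactors = FALSE
  )
  out <- df[!bad, , drop = FALSE]
  out$event_age[out$case == 0L] <- NA_real_
  rownames(out) <- NULL
  structure(out,
    class = c("binary_phenotype", "data.frame"),
    trait_code = trait_code, sex_restriction = sex_restriction,
    age_window = age_window, rejected = rejected
  )
}

#' Construct a quantitative phenotype
#'
#' @param df data.frame with `individual_id` and `value`.
#' @param trait_code short trait label (e.g. `"HDL"`).
#' @param sex_restriction optional `"female"` or `"male"`.
#' @return A `quant_phenotype` (data.frame); non-finite values are rejected.
#' @export
quant_phenotype <- function(df, trait_code, sex_restriction = NULL) {
  req <- c("individual_id", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("quantitative phenotype missing column(s): %s", paste(miss, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$value <- as.numeric(df$value)
  if (!is.null(sex_restriction)) sex_restriction <- match.arg(sex_restriction, SEX_LEVELS)
  bad <- !is.finite(df$value)
  rejected <- data.frame(
    individual_id = df$individual_id[bad],
    reason = rep("non-finite trait value", sum(bad)), stringsAsFactors = FALSE
  )
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("quant_phenotype", "data.frame"),
    trait_code = trait_code, sex_restriction = sex_restriction, rejected = rejected
  )
}

#' Construct a carrier-status table
#'
#' @param df data.frame with `individual_id` and `carrier` (0/1).
#' @param gene_set label for the gene set defining carriership (e.g. the
#'   four-gene familial-hypercholesterolemia set).
#' @return A `carrier_table` (data.frame).
#' @export
carrier_table <- function(df, gene_set = "gene_set") {
  req <- c("individual_id", "carrier")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("carrier table missing column(s): %s", paste(miss, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$carrier <- as.integer(df$carrier)
  if (!all(df$carrier %in% c(0L, 1L))) stopf("carrier flag must be 0/1")
  structure(df, class = c("carrier_table", "data.frame"), gene_set = gene_set)
}

# ---- tab-separated dialect -------------------------------------------------
# UTF-8, header required, tab separator, "NA" or empty = missing. Column-name
# mapping is configurable so files with arbitrary headers can be ingested.

read_tsv_dialect <- function(path, columns = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path,
    sep = "\t", header = TRUE, na.strings = c("NA", ""),
    stringsAsFactors = FALSE, check.names = FALSE, fileEncoding = "UTF-8"
  )
  if (!is.null(columns)) {
    miss <- setdiff(unname(unlist(columns)), names(df))
    if (length(miss)) {
      stopf("configured column(s) absent from %s: %s", path, paste(miss, collapse = ", "))
    }
    for (canonical in names(columns)) {
      names(df)[names(df) == columns[[canonical]]] <- canonical
    }
  }
  df
}

#' Read a cohort table from a tab-separated file
#'
#' @param path file path.
#' @param columns optional named list mapping canonical column names
#'   (`individual_id`, `sex`, ...) to the file's header names.
#' @param parents_path optional path to a tab-separated parental table
#'   (`individual_id`, `parent_sex`, `parent_age`, `parent_dead`).
#' @inheritParams cohort_table
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, columns = NULL, parents_path = NULL,
                        incidence_mode = c("lifetime", "incident")) {
  df <- read_tsv_dialect(path, columns)
  parents <- if (!is.null(parents_path)) read_tsv_dialect(parents_path) else NULL
  cohort_table(df, parents = parents, incidence_mode = match.arg(incidence_mode))
}

#' Read a score set from a tab-separated file
#'
#' @inheritParams read_cohort
#' @param meta optional score metadata data.frame (see [score_set()]).
#' @return A [score_set()].
#' @export
read_scores <- function(path, columns = NULL, meta = NULL) {
  score_set(read_tsv_dialect(path, columns), meta = meta)
}

#' Read a phenotype table from a tab-separated file
#'
#' @inheritParams read_cohort
#' @param trait_code short trait label.
#' @param type `"binary"` or `"quantitative"`.
#' @param ... passed to [binary_phenotype()] or [quant_phenotype()].
#' @return A [binary_phenotype()] or [quant_phenotype()].
#' @export
read_phenotype <- function(path, trait_code, type = c("binary", "quantitative"),
                           columns = NULL, ...) {
  type <- match.arg(type)
  df <- read_tsv_dialect(path, columns)
  if (type == "binary") binary_phenotype(df, trait_code, ...) else quant_phenotype(df, trait_code, ...)
}

#' Read a carrier-status table from a tab-separated file
#'
#' @inheritParams read_cohort
#' @param gene_set gene-set label.
#' @return A [carrier_table()].
#' @export
read_carriers <- function(path, gene_set = "gene_set", columns = NULL) {
  carrier_table(read_tsv_dialect(path, columns), gene_set = gene_set)
}

#' Write a table in the package's tab-separated dialect
#'
#' Values round-trip bit-exactly through [read_cohort()] and friends for the
#' supported column types (character, integer, double written with full
#' precision).
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_dialect <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df[[j]][is.na(x[[j]])] <- NA
  }
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA", fileEncoding = "UTF-8"
  )
  invisible(path)
}

# ---- alignment -------------------------------------------------------------

#' Align cohort, scores and a phenotype into one analysis frame
#'
#' Inner join on `individual_id` (complete-case: rows missing the chosen
#' score or the phenotype are dropped per analysis). Sex restrictions on the
#' phenotype are applied by excluding the other sex. Dropped counts from each
#' side are recorded in `attr(, "dropped")`.
#'
#' @param cohort a [cohort_table()].
#' @param scores a [score_set()].
#' @param pheno a [binary_phenotype()] or [quant_phenotype()].
#' @param score_name which score column to analyse (default: the first whose
#'   trait code matches the phenotype's, else the first column).
#' @param keep_scores keep all score columns (needed by
#'   [bootstrap_compare()]); the analysed one is duplicated as `prs`.
#' @return A `prs_frame` data.frame with columns `individual_id`, `sex`,
#'   `age_at_assessment`, `ancestry`, `censor_age`, `death_age`, `prs` and
#'   the phenotype columns (`case`/`event_age` or `value`).
#' @export
align <- function(cohort, scores, pheno, score_name = NULL, keep_scores = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(scores, "score_set"))
  meta <- attr(scores, "meta")
  score_cols <- setdiff(names(scores), "individual_id")
  if (is.null(score_name)) {
    hit <- meta$score_name[meta$trait_code == attr(pheno, "trait_code")]
    score_name <- if (length(hit)) hit[1] else score_cols[1]
  }
  if (!(score_name %in% score_cols)) stopf("unknown score column: %s", score_name)

  sc <- as.data.frame(scores)[, c("individual_id", if (keep_scores) score_cols else score_name), drop = FALSE]
  sc <- sc[!is.na(sc[[score_name]]), , drop = FALSE]
  ph <- as.data.frame(pheno)
  ph_cols <- intersect(c("case", "event_age", "value"), names(ph))
  if ("value" %in% ph_cols) ph <- ph[!is.na(ph$value), , drop = FALSE]
  if ("case" %in% ph_cols) ph <- ph[!is.na(ph$case), , drop = FALSE]

  ids <- intersect(as.data.frame(cohort)$individual_id, intersect(sc$individual_id, ph$individual_id))
  dropped <- c(
    cohort = nrow(cohort) - length(ids),
    scores = nrow(sc) - length(ids),
    phenotype = nrow(ph) - length(ids)
  )
  if (!length(ids)) stopf("no individuals shared between cohort, scores and phenotype")

  co <- as.data.frame(cohort)
  out <- co[match(ids, co$individual_id), c("individual_id", "sex", "age_at_assessment", "ancestry", "censor_age", "death_age")]
  out$prs <- sc[[score_name]][match(ids, sc$individual_id)]
  if (keep_scores) {
    for (s in score_cols) out[[s]] <- sc[[s]][match(ids, sc$individual_id)]
  }
  for (cc in ph_cols) out[[cc]] <- ph[[cc]][match(ids, ph$individual_id)]

  restrict <- attr(pheno, "sex_restriction")
  dropped_sex <- 0L
  if (!is.null(restrict)) {
    keep <- !is.na(out$sex) & out$sex == restrict
    dropped_sex <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  if (!nrow(out)) stopf("alignment left no individuals after sex restriction")
  # stable key order makes every downstream estimate independent of row order
  out <- out[order(out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("prs_frame", "data.frame"),
    trait_code = attr(pheno, "trait_code"),
    trait_type = if ("value" %in% ph_cols) "quantitative" else "binary",
    score_name = score_name,
    source = meta$source[match(score_name, meta$score_name)],
    sex_restriction = restrict,
    age_window = attr(pheno, "age_window"),
    incidence_mode = attr(cohort, "incidence_mode"),
    dropped = c(dropped, sex_restricted = dropped_sex)
  )
}

#' Per-ancestry raw-score distribution summary
#'
#' Mean and standard deviation (n - 1 denominator) of each raw PRS within
#' each ancestry group, as in a release's score-distribution table.
#'
#' @param scores a [score_set()].
#' @param cohort a [cohort_table()] supplying the ancestry labels.
#' @param include_other include the `"other"`/unclassified ancestry label
#'   (default `FALSE`).
#' @return data.frame with columns `score_name`, `ancestry`, `n`, `mean`,
#'   `sd` and `degenerate` (`TRUE` when the score is constant; `sd` is `NA`
#'   when `n < 2`).
#' @export
distribution_summary <- function(scores, cohort, include_other = FALSE) {
  co <- as.data.frame(cohort)
  sc <- as.data.frame(scores)
  ids <- intersect(co$individual_id, sc$individual_id)
  anc <- co$ancestry[match(ids, co$individual_id)]
  groups <- sort(unique(anc))
  if (!include_other) groups <- setdiff(groups, c("other", "unclassified"))
  score_cols <- setdiff(names(sc), "individual_id")
  rows <- list()
  for (s in score_cols) {
    v <- sc[[s]][match(ids, sc$individual_id)]
    for (g in groups) {
      x <- v[anc == g & !is.na(v)]
      n <- length(x)
      sdev <- if (n >= 2) sd(x) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        score_name = s, ancestry = g, n = n,
        mean = if (n) mean(x) else NA_real_, sd = sdev,
        degenerate = isTRUE(!is.na(sdev) && sdev == 0),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d individuals, %d ancestry group(s), incidence mode '%s'\n",
    nrow(x), length(unique(x$ancestry)), attr(x, "incidence_mode")
  ))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) cat(sprintf("  %d row(s) rejected at validation\n", nrow(rej)))
  if (!is.null(attr(x, "parents"))) cat(sprintf("  %d parental observation(s)\n", nrow(attr(x, "parents"))))
  invisible(x)
}
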