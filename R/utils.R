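#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm lm coef vcov qnorm pnorm rnorm runif rbinom quantile
#'   sd var cor complete.cases binomial optimize setNames as.formula
#'   model.matrix hclust dist predict plogis
#' @importFrom utils head read.delim write.table modifyList
#' @importFrom survival Surv coxph survfit concordance
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one root seed through named
#' sub-streams, so that (for example) adding a trait to a simulation never
#' perturbs the draws of another trait. The sub-seed is a deterministic
#' 31-bit hash of the root seed and the stream name.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 48271) %% m
  as.integer(max(1, h %% (m - 1)))
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# significance stars used in stratified summary tables
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# stable content hash (FNV-1a over a canonical JSON rendering), for provenance
content_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE, null = "null")
  h <- 2166136261
  for (ch in utf8ToInt(as.character(txt))) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (as.double(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# two-sided normal p-value from a z statistic
z_pvalue <- function(z) 2 * pnorm(-abs(z))
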