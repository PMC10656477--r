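#' @importFrom stats cor median p.adjust ppois qpois rbinom rnorm rpois runif
#'   sd setNames t.test fisher.test uniroot var quantile rmultinom logLik
#' @importFrom utils head read.delim write.table tail
NULL

# Shared validation helpers. All genomic coordinates inside the package are
# 0-based half-open; conversion happens only at the GFF3 boundary.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_intervals <- function(df, what = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .stopf("%s table lacks column(s): %s", what, paste(miss, collapse = ", "))
  if (any(df$start < 0L))
    .stopf("%s has negative start coordinate", what)
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L)
    .stopf("%s has end <= start at row %d", what, bad[1L])
  invisible(df)
}

#' Deterministic genomic sort
#'
#' Orders an interval table by chromosome (lexical), start, end and strand.
#' Applied before any on-disk output so that repeated runs diff cleanly.
#'
#' @param df data.frame with at least `chrom`, `start`, `end` columns and
#'   optionally `strand`.
#' @return the same data.frame, reordered, row names dropped.
#' @export
sort_intervals <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep("+", nrow(df))
  ord <- order(df$chrom, df$start, df$end, strand, method = "radix")
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps simulation determinism local.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive k reproducible 31-bit sub-seeds from one master seed.
.sub_seeds <- function(seed, k) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
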