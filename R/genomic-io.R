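# Readers and writers for the plain-text formats used across the pipeline,
# plus the shared interval arithmetic. Coordinates are 0-based half-open
# internally; BED files are native, GFF3 is converted at the boundary.

#' Read a BED file
#'
#' Reads BED3/BED4/BED6 into a data.frame of 0-based half-open intervals.
#' Input order is preserved.
#'
#' @param path path to a tab-separated BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("malformed BED line %d: fewer than 3 columns", which(nf < 3L)[1L])
  ncol <- max(nf)
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else ".", "")
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L)
    .stopf("malformed BED line %d: non-integer coordinates", bad[1L])
  df <- data.frame(chrom = get(1L), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol >= 4L) df$name <- get(4L)
  if (ncol >= 5L) df$score <- suppressWarnings(as.numeric(get(5L)))
  if (ncol >= 6L) df$strand <- get(6L)
  .check_intervals(df, "BED")
  df
}

#' Write a BED file
#'
#' Writes intervals as BED3-BED6 after the package's deterministic sort.
#'
#' @param df interval data.frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path output path.
#' @return invisibly, the sorted data.frame that was written.
#' @export
write_bed <- function(df, path) {
  .check_intervals(df, "BED")
  df <- sort_intervals(df)
  cols <- c("chrom", "start", "end")
  if ("strand" %in% names(df)) {
    if (!"name" %in% names(df)) df$name <- "."
    if (!"score" %in% names(df)) df$score <- 0
    cols <- c(cols, "name", "score", "strand")
  } else {
    if ("name" %in% names(df)) cols <- c(cols, "name")
  }
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file with a gene/mRNA/exon (+ optional five_prime_UTR)
#' hierarchy into one row per gene. GFF3 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention; the TSS is the
#' 5' end of the first exon (start on `+`, end-1 on `-`).
#'
#' @param path GFF3 file path.
#' @return list with `genes` (data.frame: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`) and interval data.frames `utr5` and `exons`,
#'   each carrying a `gene_id` column.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) .stopf("GFF3 file has no feature lines: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    .stopf("malformed GFF3 line %d: expected 9 columns", which(nf != 9L)[1L])
  m <- do.call(rbind, fields)
  start1 <- as.integer(m[, 4L])
  end1 <- as.integer(m[, 5L])
  if (any(is.na(start1) | is.na(end1)))
    .stopf("malformed GFF3 coordinates at line %d",
           which(is.na(start1) | is.na(end1))[1L])
  if (any(end1 < start1))
    .stopf("GFF3 end < start at line %d", which(end1 < start1)[1L])
  type <- m[, 3L]
  attr_field <- m[, 9L]
  get_attr <- function(key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    val <- regmatches(attr_field, regexpr(pat, attr_field, perl = TRUE))
    out <- rep(NA_character_, length(attr_field))
    hit <- grepl(pat, attr_field, perl = TRUE)
    out[hit] <- sub(pat, "\\1", regmatches(attr_field,
                                           regexpr(pat, attr_field, perl = TRUE)))
    out
  }
  id <- get_attr("ID")
  parent <- get_attr("Parent")
  feat <- data.frame(chrom = m[, 1L], type = type,
                     start = start1 - 1L, end = end1,  # to 0-based half-open
                     strand = m[, 7L], id = id, parent = parent,
                     stringsAsFactors = FALSE)
  genes <- feat[feat$type == "gene", , drop = FALSE]
  mrna <- feat[feat$type == "mRNA", , drop = FALSE]
  if (nrow(genes) == 0L || nrow(mrna) == 0L)
    .stopf("GFF3 lacks a gene/mRNA feature hierarchy: %s", path)
  if (anyNA(genes$id)) .stopf("GFF3 gene feature without ID attribute")
  mrna2gene <- setNames(mrna$parent, mrna$id)
  if (anyNA(mrna2gene)) .stopf("GFF3 mRNA feature without Parent attribute")
  child_gene <- function(sub) {
    g <- mrna2gene[sub$parent]
    g[is.na(g)] <- sub$parent[is.na(g)]  # children attached to genes directly
    g
  }
  exons <- feat[feat$type == "exon", , drop = FALSE]
  if (nrow(exons) == 0L) .stopf("GFF3 has no exon features: %s", path)
  exons$gene_id <- unname(child_gene(exons))
  utr5 <- feat[feat$type == "five_prime_UTR", , drop = FALSE]
  utr5$gene_id <- if (nrow(utr5) > 0L) unname(child_gene(utr5)) else character()
  tss <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$gene_id == genes$id[i], , drop = FALSE]
    if (nrow(ex) == 0L) .stopf("gene %s has no exons", genes$id[i])
    if (genes$strand[i] == "-") max(ex$end) - 1L else min(ex$start)
  }, integer(1))
  list(
    genes = data.frame(gene_id = genes$id, chrom = genes$chrom,
                       start = genes$start, end = genes$end,
                       strand = genes$strand, tss = tss,
                       stringsAsFactors = FALSE),
    utr5 = data.frame(gene_id = utr5$gene_id, chrom = utr5$chrom,
                      start = utr5$start, end = utr5$end,
                      strand = utr5$strand, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = exons$gene_id, chrom = exons$chrom,
                       start = exons$start, end = exons$end,
                       strand = exons$strand, stringsAsFactors = FALSE)
  )
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_genes()]: emits gene/mRNA/exon/five_prime_UTR rows,
#' converting internal 0-based half-open coordinates back to 1-based
#' inclusive GFF3.
#'
#' @param gene_models list as returned by [read_gff3_genes()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3_genes <- function(gene_models, path) {
  g <- sort_intervals(gene_models$genes)
  row <- function(chrom, type, start0, end0, strand, attrs) {
    paste(chrom, "eletools", type, start0 + 1L, end0, ".", strand, ".",
          attrs, sep = "\t")
  }
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    out <- c(out,
             row(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                 paste0("ID=", gid)),
             row(g$chrom[i], "mRNA", g$start[i], g$end[i], g$strand[i],
                 paste0("ID=", gid, ".1;Parent=", gid)))
    ex <- gene_models$exons[gene_models$exons$gene_id == gid, , drop = FALSE]
    ex <- sort_intervals(ex)
    for (j in seq_len(nrow(ex)))
      out <- c(out, row(ex$chrom[j], "exon", ex$start[j], ex$end[j],
                        ex$strand[j], paste0("Parent=", gid, ".1")))
    u5 <- gene_models$utr5[gene_models$utr5$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(u5)))
      out <- c(out, row(u5$chrom[j], "five_prime_UTR", u5$start[j], u5$end[j],
                        u5$strand[j], paste0("Parent=", gid, ".1")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a CTSS count table
#'
#' Reads the stranded per-position CAGE 5'-end count table. The header row
#' names one count column per sample as `tissue_repN`.
#'
#' @param path tab-delimited file with columns `chrom`, `pos`, `strand`,
#'   then one integer count column per sample.
#' @return object of class `ctss_table`: list with `positions` (data.frame
#'   `chrom`, `pos`, `strand`), `counts` (integer matrix, one column per
#'   sample), and `samples` (data.frame `sample`, `tissue`, `replicate`).
#' @export
read_ctss <- function(path) {
  if (!file.exists(path)) .stopf("CTSS table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(df)))
    .stopf("CTSS table must have columns chrom, pos, strand")
  sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) == 0L) .stopf("CTSS table has no sample columns")
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(counts) <- "integer"
  ctss_table(df[, need], counts)
}

#' Construct a CTSS table
#'
#' @param positions data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param counts non-negative integer matrix, rows matching `positions`,
#'   column names `tissue_repN`.
#' @return `ctss_table` object; rows deterministically sorted and unique per
#'   (chrom, pos, strand).
#' @export
ctss_table <- function(positions, counts) {
  if (nrow(positions) != nrow(counts))
    .stopf("positions and counts row counts differ")
  if (any(counts < 0)) .stopf("negative CTSS counts")
  if (any(positions$pos < 0)) .stopf("negative CTSS position")
  samples <- .parse_sample_ids(colnames(counts))
  key <- paste(positions$chrom, positions$pos, positions$strand)
  if (anyDuplicated(key) > 0L)
    .stopf("duplicate (chrom, pos, strand) in CTSS table")
  ord <- order(positions$chrom, positions$pos, positions$strand,
               method = "radix")
  out <- list(positions = `rownames<-`(positions[ord, , drop = FALSE], NULL),
              counts = counts[ord, , drop = FALSE],
              samples = samples)
  class(out) <- "ctss_table"
  out
}

.parse_sample_ids <- function(ids) {
  if (is.null(ids)) .stopf("CTSS count matrix must have sample column names")
  m <- regmatches(ids, regexec("^(.+)_rep([0-9]+)$", ids))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    .stopf("sample id '%s' is not of the form tissue_repN", ids[bad][1L])
  data.frame(sample = ids,
             tissue = vapply(m, `[[`, "", 2L),
             replicate = as.integer(vapply(m, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' @export
print.ctss_table <- function(x, ...) {
  cat(sprintf("ctss_table: %d positions, %d samples (%d tissues)\n",
              nrow(x$positions), nrow(x$samples),
              length(unique(x$samples$tissue))))
  cat(sprintf("  total tags: %d\n", sum(x$counts)))
  invisible(x)
}

#' Write a CTSS count table
#'
#' @param ctss `ctss_table` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ctss <- function(ctss, path) {
  df <- cbind(ctss$positions, as.data.frame(ctss$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transposable-element annotation table
#'
#' Tab-delimited with header: `te_id`, `chrom`, `start`, `end`, `strand`,
#' `superfamily`, `family`, `subfamily`, `full_length` (TRUE/FALSE),
#' `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end` (LTR columns NA for
#' non-full-length elements). Subfamily labels must be prefixed by their
#' family label (e.g. RLG_famc7.3 under RLG_famc7), the family by its
#' superfamily.
#'
#' @param path file path.
#' @return data.frame of TE annotations, 0-based half-open.
#' @export
read_te_table <- function(path) {
  if (!file.exists(path)) .stopf("TE table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_te_table(df)
}

#' Validate a TE annotation table
#'
#' @param df candidate TE table (see [read_te_table()] for columns).
#' @return the validated data.frame.
#' @export
validate_te_table <- function(df) {
  .check_intervals(df, "TE")
  need <- c("te_id", "superfamily", "family", "subfamily", "full_length")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .stopf("TE table lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!startsWith(df$subfamily, df$family))
  if (length(bad) > 0L)
    .stopf("TE row %d: subfamily '%s' not prefixed by family '%s'",
           bad[1L], df$subfamily[bad[1L]], df$family[bad[1L]])
  bad <- which(!startsWith(df$family, df$superfamily))
  if (length(bad) > 0L)
    .stopf("TE row %d: family '%s' not prefixed by superfamily '%s'",
           bad[1L], df$family[bad[1L]], df$superfamily[bad[1L]])
  fl <- which(df$full_length)
  for (i in fl) {
    ltr <- c(df$ltr5_start[i], df$ltr5_end[i], df$ltr3_start[i], df$ltr3_end[i])
    if (anyNA(ltr))
      .stopf("full-length TE %s lacks LTR sub-intervals", df$te_id[i])
    if (ltr[1L] < df$start[i] || ltr[4L] > df$end[i] ||
        ltr[2L] <= ltr[1L] || ltr[4L] <= ltr[3L] || ltr[3L] < ltr[2L])
      .stopf("TE %s: LTR sub-intervals outside element span or malformed",
             df$te_id[i])
  }
  nfl <- which(!df$full_length)
  if (length(nfl) > 0L && "ltr5_start" %in% names(df)) {
    if (any(!is.na(df$ltr5_start[nfl])))
      .stopf("non-full-length TE carries LTR sub-intervals")
  }
  df
}

#' Write a TE annotation table
#'
#' @param df TE table (see [read_te_table()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_te_table <- function(df, path) {
  df <- sort_intervals(validate_te_table(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cytosine methylation table
#'
#' Tab-delimited with header: `chrom`, `pos`, `strand`, `context` (CG, CHG
#' or CHH), `methylated_reads`, `total_reads`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) .stopf("methylation table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "methylated_reads",
            "total_reads")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .stopf("methylation table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(!df$context %in% c("CG", "CHG", "CHH")))
    .stopf("methylation context must be CG, CHG or CHH")
  if (any(df$methylated_reads < 0L) ||
      any(df$methylated_reads > df$total_reads))
    .stopf("methylated_reads must lie in [0, total_reads]")
  df
}

#' Per-cytosine methylation ratio with a coverage floor
#'
#' The ratio is methylated reads over covering reads; positions covered by
#' fewer than `min_coverage` reads (default 3) are low-confidence and
#' masked as `NA`.
#'
#' @param methylated_reads,total_reads integer vectors.
#' @param min_coverage minimum read coverage; below it the ratio is `NA`.
#' @return numeric vector of ratios in `[0, 1]`, `NA` where masked.
#' @export
methylation_ratio <- function(methylated_reads, total_reads,
                              min_coverage = 3L) {
  if (any(methylated_reads < 0L) || any(methylated_reads > total_reads))
    .stopf("methylated_reads must lie in [0, total_reads]")
  ratio <- methylated_reads / total_reads
  ratio[total_reads < min_coverage] <- NA_real_
  ratio
}

#' Overlap query over an interval set
#'
#' Returns the subjects overlapping the query under half-open semantics
#' (A overlaps B iff A.start < B.end and B.start < A.end), restricted to the
#' query's chromosome, ordered by (start, end). Backed by IRanges.
#'
#' @param query one-row interval data.frame (`chrom`, `start`, `end`).
#' @param subjects interval data.frame.
#' @return subset of `subjects`, deterministically ordered.
#' @export
overlap_query <- function(query, subjects) {
  hits <- overlap_pairs(query, subjects)
  out <- subjects[hits$subject, , drop = FALSE]
  ord <- order(out$start, out$end, method = "radix")
  `rownames<-`(out[ord, , drop = FALSE], NULL)
}

# All overlapping (query, subject) row-index pairs between two interval
# tables, same chromosome, half-open semantics. IRanges does the sweep.
overlap_pairs <- function(query, subjects) {
  if (nrow(query) == 0L || nrow(subjects) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  q <- IRanges::IRanges(start = query$start + 1L, end = query$end)
  s <- IRanges::IRanges(start = subjects$start + 1L, end = subjects$end)
  hits <- IRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- query$chrom[qi] == subjects$chrom[si]
  data.frame(query = qi[same], subject = si[same])
}

# Distance between two half-open intervals on one chromosome: 0 when they
# overlap or touch, else the gap width.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1, start2) - pmin(end1, end2))
}
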