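# TE-embedded ELE analysis: point assignment of ELEs to TE copies,
# family/subfamily and tissue-bias enrichment via two-tailed Fisher's
# exact tests with BH correction, LTR retrotransposon insertion-time
# dating from Kimura two-parameter LTR divergence, and motif-abundance
# comparison between ELE groups.

#' Assign ELEs to transposable elements
#'
#' An ELE is TE-embedded iff its dominant position lies inside a TE
#' interval; when nested TEs contain the point, the shortest (innermost)
#' element wins (ties by start, then end).
#'
#' @param eles data.frame with `ele_id`, `chrom`, `dominant_pos`.
#' @param te_table TE annotation data.frame (see [read_te_table()]).
#' @return `eles` with added `te_id`, `superfamily`, `family`, `subfamily`
#'   columns (`NA` for non-TE ELEs).
#' @export
assign_te <- function(eles, te_table) {
  out <- eles
  out$te_id <- NA_character_
  out$superfamily <- NA_character_
  out$family <- NA_character_
  out$subfamily <- NA_character_
  if (nrow(eles) == 0L || nrow(te_table) == 0L) return(out)
  pts <- data.frame(chrom = eles$chrom, start = eles$dominant_pos,
                    end = eles$dominant_pos + 1L)
  hits <- overlap_pairs(pts, te_table)
  if (nrow(hits) == 0L) return(out)
  w <- te_table$end[hits$subject] - te_table$start[hits$subject]
  ord <- order(hits$query, w, te_table$start[hits$subject],
               te_table$end[hits$subject], method = "radix")
  first <- !duplicated(hits$query[ord])
  qi <- hits$query[ord][first]
  si <- hits$subject[ord][first]
  out$te_id[qi] <- te_table$te_id[si]
  out$superfamily[qi] <- te_table$superfamily[si]
  out$family[qi] <- te_table$family[si]
  out$subfamily[qi] <- te_table$subfamily[si]
  out
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' p is the sum of hypergeometric probabilities, over all tables with the
#' observed margins, that do not exceed the observed table's probability
#' (the conventional two-tailed rule). The odds ratio is the sample
#' estimate `ad/bc` (`NA` for 0/0, `Inf` for x/0).
#'
#' @param a,b,c_,d_ non-negative integer cell counts (row1: a, b; row2:
#'   c_, d_).
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  cells <- c(a, b, c_, d_)
  if (any(cells < 0) || any(cells != floor(cells)))
    .stopf("cells must be non-negative integers")
  if (sum(cells) == 0) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  p <- fisher.test(matrix(cells, 2L, byrow = TRUE))$p.value
  or <- if (b == 0 && c_ == 0) {
    if (a == 0 || d_ == 0) NA_real_ else Inf
  } else if (b * c_ == 0) {
    if (a * d_ == 0) NA_real_ else Inf
  } else a * d_ / (b * c_)
  list(odds_ratio = or, p = min(p, 1))
}

.enrichment_frame <- function(groups, tabs) {
  res <- data.frame(group = groups,
                    a = vapply(tabs, `[[`, 0, 1L),
                    b = vapply(tabs, `[[`, 0, 2L),
                    c = vapply(tabs, `[[`, 0, 3L),
                    d = vapply(tabs, `[[`, 0, 4L),
                    stringsAsFactors = FALSE)
  ft <- lapply(seq_len(nrow(res)),
               function(i) fisher_exact_2x2(res$a[i], res$b[i], res$c[i],
                                            res$d[i]))
  res$odds_ratio <- vapply(ft, `[[`, 0, "odds_ratio")
  res$p <- vapply(ft, `[[`, 0, "p")
  res$q <- p.adjust(res$p, method = "BH")
  # transposed tables give mathematically equal p; round before ordering so
  # the descending-odds-ratio tie-break is not defeated by float noise
  res[order(signif(res$p, 12), -res$odds_ratio, res$group, na.last = TRUE),
      , drop = FALSE]
}

#' TE family/subfamily enrichment for ELE generation
#'
#' For each TE group at the chosen level, tests whether its copies bear
#' ELEs more often than the rest of the genome's TEs: 2x2 of (ELE-bearing
#' vs not) x (group vs other TEs), two-tailed Fisher, BH-adjusted across
#' groups. The whole genome's TE complement is the background.
#'
#' @param te_assign output of [assign_te()] (only TE-embedded rows are
#'   used).
#' @param te_table full TE annotation.
#' @param level `"family"` or `"subfamily"`.
#' @return data.frame per group: cells `a`-`d`, `odds_ratio`, `p`, `q`,
#'   ordered by increasing p.
#' @export
family_enrichment <- function(te_assign, te_table,
                              level = c("subfamily", "family")) {
  level <- match.arg(level)
  bearing <- unique(te_assign$te_id[!is.na(te_assign$te_id)])
  te_table$bearing <- te_table$te_id %in% bearing
  groups <- sort(unique(te_table[[level]]))
  tabs <- lapply(groups, function(gp) {
    ingrp <- te_table[[level]] == gp
    c(sum(ingrp & te_table$bearing), sum(ingrp & !te_table$bearing),
      sum(!ingrp & te_table$bearing), sum(!ingrp & !te_table$bearing))
  })
  .enrichment_frame(groups, tabs)
}

#' Tissue-bias enrichment of TE-ELE groups
#'
#' For each (TE group, tissue), tests whether ELEs of the group are
#' enriched among ELEs specific to that tissue, with all ELEs as the
#' background: 2x2 of (in group vs not) x (specific to tissue vs not).
#'
#' @param te_assign output of [assign_te()] for all ELEs.
#' @param specificity data.frame from [tissue_specificity()], rows matching
#'   `te_assign` rows.
#' @param level `"subfamily"` or `"family"`.
#' @return data.frame per (group, tissue) with Fisher results, BH-adjusted
#'   across all tests.
#' @export
tissue_enrichment <- function(te_assign, specificity,
                              level = c("subfamily", "family")) {
  level <- match.arg(level)
  grp <- te_assign[[level]]
  groups <- sort(unique(grp[!is.na(grp)]))
  tissues <- sort(unique(specificity$tissue[!is.na(specificity$tissue)]))
  combos <- expand.grid(group = groups, tissue = tissues,
                        stringsAsFactors = FALSE)
  if (nrow(combos) == 0L)
    return(data.frame(group = character(), tissue = character(),
                      a = numeric(), b = numeric(), c = numeric(),
                      d = numeric(), odds_ratio = numeric(), p = numeric(),
                      q = numeric()))
  tabs <- lapply(seq_len(nrow(combos)), function(i) {
    ingrp <- !is.na(grp) & grp == combos$group[i]
    spec <- specificity$label == "specific" &
      !is.na(specificity$tissue) & specificity$tissue == combos$tissue[i]
    c(sum(ingrp & spec), sum(ingrp & !spec),
      sum(!ingrp & spec), sum(!ingrp & !spec))
  })
  res <- .enrichment_frame(seq_len(nrow(combos)), tabs)
  res$tissue <- combos$tissue[res$group]
  res$group <- combos$group[res$group]
  res[, c("group", "tissue", "a", "b", "c", "d", "odds_ratio", "p", "q")]
}

# 5-letter DNA scoring matrix: match +1, mismatch -2, N neutral (0).
.dna_submat <- function(match = 1, mismatch = -2) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Globally align a 5'/3' LTR pair
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -2, gap open -5,
#' gap extend -1; a gap of length L costs 5 + L) via Biostrings.
#'
#' @param seq5,seq3 DNA strings (alphabet ACGTN).
#' @return list with `aligned5`, `aligned3` (equal-length gapped strings)
#'   and `score`.
#' @export
align_ltr_pair <- function(seq5, seq3) {
  if (nchar(seq5) == 0L || nchar(seq3) == 0L)
    .stopf("LTR sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq5), Biostrings::DNAString(seq3),
    type = "global", substitutionMatrix = .dna_submat(),
    gapOpening = 5, gapExtension = 1)
  list(aligned5 = as.character(Biostrings::alignedPattern(aln)),
       aligned3 = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Kimura two-parameter distance of an aligned pair
#'
#' Columns containing a gap or N are excluded from the site count.
#' `P` is the transition proportion (A<->G, C<->T), `Q` the transversion
#' proportion; `d = -0.5 log(1 - 2P - Q) - 0.25 log(1 - 2Q)`. When the
#' logs' arguments are non-positive the distance is saturated and returned
#' as `NA` with `saturated = TRUE`.
#'
#' @param aligned5,aligned3 equal-length aligned strings.
#' @return list with `P`, `Q`, `d`, `sites`, `saturated`.
#' @export
kimura_2p <- function(aligned5, aligned3) {
  if (nchar(aligned5) != nchar(aligned3))
    .stopf("aligned sequences must have equal length")
  x <- strsplit(toupper(aligned5), "")[[1L]]
  y <- strsplit(toupper(aligned3), "")[[1L]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) .stopf("no comparable sites in alignment")
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(list(P = P, Q = Q, d = NA_real_, sites = n, saturated = TRUE))
  list(P = P, Q = Q, d = -0.5 * log(a1) - 0.25 * log(a2), sites = n,
       saturated = FALSE)
}

#' Insertion time from LTR divergence
#'
#' `time = distance / (mu * 2 * 100)` with the distance expressed in
#' percent (the distance-matrix convention), equivalently
#' `d_k2p / (2 * mu)` generations: the two LTRs were identical at
#' insertion and each accumulates substitutions at rate `mu` per site per
#' generation.
#'
#' @param d_percent K2P distance in percent (i.e. `100 * d`).
#' @param mu substitution rate per bp per generation. Default 1.3e-8.
#' @return time in generations.
#' @export
insertion_time <- function(d_percent, mu = 1.3e-8) {
  if (any(d_percent < 0)) .stopf("distance must be non-negative")
  d_percent / (mu * 2 * 100)
}

#' Date a set of full-length LTR elements
#'
#' Aligns each 5'/3' LTR pair, computes the K2P distance, and converts it
#' to an insertion time in generations.
#'
#' @param ltr_pairs data.frame with `te_id`, `ltr5`, `ltr3` sequence
#'   columns.
#' @param mu substitution rate per bp per generation. Default 1.3e-8.
#' @return data.frame with `te_id`, `P`, `Q`, `d`, `sites`, `saturated`,
#'   `time_generations`.
#' @export
ltr_age <- function(ltr_pairs, mu = 1.3e-8) {
  res <- lapply(seq_len(nrow(ltr_pairs)), function(i) {
    aln <- align_ltr_pair(ltr_pairs$ltr5[i], ltr_pairs$ltr3[i])
    k <- kimura_2p(aln$aligned5, aln$aligned3)
    data.frame(te_id = ltr_pairs$te_id[i], P = k$P, Q = k$Q, d = k$d,
               sites = k$sites, saturated = k$saturated,
               time_generations = if (k$saturated) NA_real_
                                  else insertion_time(100 * k$d, mu),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Scan sequences with position weight matrices
#'
#' Log-odds (log2) scanning of both strands. A position is a hit when its
#' score reaches the motif's threshold; the default threshold is the
#' smallest score whose p-value under the background does not exceed
#' `p_max`, computed by exact enumeration of the lattice score
#' distribution (scores rounded to 1e-3).
#'
#' @param sequences named character vector of DNA sequences.
#' @param pwms named list of probability matrices (4 rows ACGT x motif
#'   width; columns sum to 1).
#' @param background base frequencies (A, C, G, T). Default uniform.
#' @param p_max per-position hit p-value. Default 1e-4.
#' @return integer matrix sequence x motif of hit counts.
#' @export
scan_pwm <- function(sequences, pwms, background = rep(0.25, 4),
                     p_max = 1e-4) {
  bases <- c("A", "C", "G", "T")
  background <- background / sum(background)
  counts <- matrix(0L, length(sequences), length(pwms),
                   dimnames = list(names(sequences), names(pwms)))
  for (m in seq_along(pwms)) {
    pwm <- as.matrix(pwms[[m]])
    if (nrow(pwm) != 4L) .stopf("PWM must have 4 rows (A, C, G, T)")
    if (any(abs(colSums(pwm) - 1) > 1e-6))
      .stopf("PWM '%s': columns must sum to 1", names(pwms)[m])
    rownames(pwm) <- bases
    lo <- log2(pmax(pwm, 1e-9) / background)
    thr <- .pwm_threshold(lo, background, p_max)
    for (s in seq_along(sequences)) {
      counts[s, m] <- .count_pwm_hits(sequences[[s]], lo, thr) +
        .count_pwm_hits(.revcomp(sequences[[s]]), lo, thr)
    }
  }
  counts
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Smallest score s such that P(score >= s | background) <= p_max, by exact
# convolution of per-column score distributions on a 1e-3 lattice.
.pwm_threshold <- function(lo, background, p_max) {
  scale <- 1000
  dist <- c(`0` = 1)  # named lattice-score -> probability
  for (j in seq_len(ncol(lo))) {
    sc <- round(lo[, j] * scale)
    new <- tapply(rep(dist, each = 4L) * rep(background, length(dist)),
                  rep(as.numeric(names(dist)), each = 4L) + rep(sc, length(dist)),
                  sum)
    dist <- setNames(as.numeric(new), names(new))
  }
  s <- as.numeric(names(dist))
  ord <- order(s, decreasing = TRUE)
  tailp <- cumsum(dist[ord])
  ok <- which(tailp <= p_max + 1e-12)
  if (length(ok) == 0L) {
    # short motifs cannot reach p_max even at their best score; fall back
    # to exact-consensus matches. A constant score distribution (e.g. a
    # uniform PWM) stays uninformative and never hits.
    if (length(s) < 2L) return(Inf)
    return(max(s) / scale)
  }
  min(s[ord][ok]) / scale
}

.count_pwm_hits <- function(seq, lo, thr) {
  if (!is.finite(thr)) return(0L)
  w <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1L]]
  idx <- match(chars, c("A", "C", "G", "T"))
  L <- length(idx)
  if (L < w) return(0L)
  n <- L - w + 1L
  scores <- numeric(n)
  for (j in seq_len(w)) {
    v <- lo[idx[j:(j + n - 1L)], j]
    v[is.na(v)] <- -Inf  # non-ACGT character voids the window
    scores <- scores + v
  }
  # compare on the same lattice used for the threshold
  sum(round(scores * 1000) / 1000 >= thr - 1e-9)
}

#' Compare motif abundance between two ELE groups
#'
#' Normalized abundance is total occurrences over group size (per-TSS
#' normalization); group means are compared per motif with a two-tailed
#' Welch t-test on per-sequence counts. Groups of size < 2 give a missing
#' p; zero-variance separation gives p = 0 with an infinite t.
#'
#' @param counts_a,counts_b hit-count matrices (sequence x motif) from
#'   [scan_pwm()] for the two groups, same motif columns.
#' @return data.frame per motif: `abundance_a`, `abundance_b`, `t`, `p`.
#' @export
compare_motif_abundance <- function(counts_a, counts_b) {
  if (!identical(colnames(counts_a), colnames(counts_b)))
    .stopf("motif columns of the two groups differ")
  res <- lapply(colnames(counts_a), function(m) {
    xa <- counts_a[, m]; xb <- counts_b[, m]
    ab_a <- sum(xa) / length(xa)
    ab_b <- sum(xb) / length(xb)
    if (length(xa) < 2L || length(xb) < 2L) {
      t_stat <- NA_real_; p <- NA_real_
    } else if (var(xa) == 0 && var(xb) == 0) {
      if (ab_a == ab_b) { t_stat <- 0; p <- 1 }
      else { t_stat <- sign(ab_a - ab_b) * Inf; p <- 0 }
    } else {
      tt <- t.test(xa, xb)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(motif = m, abundance_a = ab_a, abundance_b = ab_b,
               t = t_stat, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Metaprofile of a track around anchors
#'
#' Averages a per-position track in fixed-width bins across stranded
#' anchor positions, rows oriented 5' to 3'. Anchors closer than `flank`
#' to a chromosome edge have the out-of-range bins set to `NA`; the mean
#' profile ignores missing values.
#'
#' @param track data.frame with `chrom`, `pos` (0-based), `value`.
#' @param anchors data.frame with `chrom`, `pos`, `strand`.
#' @param flank half-window in bp. Default 3000.
#' @param bin bin width in bp. Default 50.
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   detect right-edge truncation.
#' @return list with `matrix` (anchor x bin) and `profile` (columnwise
#'   mean); bin centers as column names (negative = upstream).
#' @export
metaprofile <- function(track, anchors, flank = 3000L, bin = 50L,
                        chrom_sizes = NULL) {
  nb <- as.integer(2L * flank / bin)
  edges <- seq(-flank, flank, by = bin)
  mat <- matrix(NA_real_, nrow(anchors), nb)
  colnames(mat) <- edges[-length(edges)] + bin / 2
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    idx <- by_chrom[[ch]]
    rel <- if (is.null(idx)) numeric() else track$pos[idx] - anchors$pos[i]
    if (identical(anchors$strand[i], "-")) rel <- -rel
    inside <- rel >= -flank & rel < flank
    b <- floor((rel[inside] + flank) / bin) + 1L
    v <- if (is.null(idx)) numeric() else track$value[idx][inside]
    row <- rep(NA_real_, nb)
    # bins fully inside the chromosome get a value (0 when no track point)
    lo_ok <- anchors$pos[i] - flank >= 0
    hi <- if (is.null(chrom_sizes)) Inf else chrom_sizes[[ch]]
    hi_ok <- anchors$pos[i] + flank <= hi
    valid <- rep(TRUE, nb)
    if (identical(anchors$strand[i], "-")) {
      if (!lo_ok) valid[seq(nb / 2 + 1, nb)] <- FALSE
      if (!hi_ok) valid[seq_len(nb / 2)] <- FALSE
    } else {
      if (!lo_ok) valid[seq_len(nb / 2)] <- FALSE
      if (!hi_ok) valid[seq(nb / 2 + 1, nb)] <- FALSE
    }
    row[valid] <- 0
    if (length(b) > 0L) {
      agg <- tapply(v, b, mean)
      row[as.integer(names(agg))] <- ifelse(valid[as.integer(names(agg))],
                                            agg, NA_real_)
    }
    mat[i, ] <- row
  }
  list(matrix = mat, profile = colMeans(mat, na.rm = TRUE))
}
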