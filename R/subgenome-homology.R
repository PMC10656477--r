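# Cross-subgenome homology classification of ELEs. Collinear gene anchors
# are chained by longest-increasing-subsequence over a supplied homoeolog
# mapping; the regions between consecutive anchors are syntenic blocks;
# each ELE's TSS + 200 bp downstream is locally aligned within the
# counterpart block and scored with Karlin-Altschul statistics; hits are
# classified by whether the homologous locus carries active marks.

#' Collinear anchor pairs between two subgenomes
#'
#' From a two-column homoeolog mapping, retains the pairs forming the
#' longest chain with strictly increasing gene positions in both
#' subgenomes (longest increasing subsequence per chromosome pair);
#' chains shorter than `min_chain` are dropped.
#'
#' @param genes1,genes2 gene data.frames (`gene_id`, `chrom`, `start`,
#'   `end`, `tss`).
#' @param homeologs data.frame with columns `gene1`, `gene2`.
#' @param min_chain minimum chain length. Default 3.
#' @return data.frame of anchor pairs (`gene1`, `gene2`, `chrom1`,
#'   `chrom2`), ordered along subgenome 1.
#' @export
collinear_anchors <- function(genes1, genes2, homeologs, min_chain = 3L) {
  if (is.null(homeologs) || nrow(homeologs) == 0L)
    .stopf("a homoeolog mapping is required")
  i1 <- match(homeologs$gene1, genes1$gene_id)
  i2 <- match(homeologs$gene2, genes2$gene_id)
  ok <- !is.na(i1) & !is.na(i2)
  h <- data.frame(gene1 = homeologs$gene1[ok], gene2 = homeologs$gene2[ok],
                  chrom1 = genes1$chrom[i1[ok]], chrom2 = genes2$chrom[i2[ok]],
                  pos1 = genes1$start[i1[ok]], pos2 = genes2$start[i2[ok]],
                  stringsAsFactors = FALSE)
  out <- lapply(split(h, paste(h$chrom1, h$chrom2)), function(df) {
    df <- df[order(df$pos1), , drop = FALSE]
    keep <- .lis(df$pos2)
    if (length(keep) < min_chain) return(NULL)
    df[keep, c("gene1", "gene2", "chrom1", "chrom2"), drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene1 = character(), gene2 = character(),
                      chrom1 = character(), chrom2 = character())
  rownames(out) <- NULL
  out
}

# Indices of one longest strictly increasing subsequence (leftmost
# tie-break, O(n log n) patience sorting).
.lis <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  tails <- integer(0)     # index of smallest tail of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    vals <- x[tails]
    j <- findInterval(x[i] - 1L, vals) + 1L  # first tail >= x[i]
    prev[i] <- if (j > 1L) tails[j - 1L] else 0L
    tails[j] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

#' Syntenic blocks between consecutive collinear anchors
#'
#' One block per consecutive anchor pair within a chain: the interval
#' strictly between the two anchor genes in each subgenome.
#'
#' @param anchors output of [collinear_anchors()].
#' @param genes1,genes2 gene data.frames.
#' @return data.frame with `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2` and flanking anchor gene ids.
#' @export
build_blocks <- function(anchors, genes1, genes2) {
  empty <- data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      anchor_left = character(), anchor_right = character())
  if (nrow(anchors) < 2L) return(empty)
  g1 <- genes1[match(anchors$gene1, genes1$gene_id), ]
  g2 <- genes2[match(anchors$gene2, genes2$gene_id), ]
  out <- lapply(split(seq_len(nrow(anchors)),
                      paste(anchors$chrom1, anchors$chrom2)), function(idx) {
    if (length(idx) < 2L) return(NULL)
    idx <- idx[order(g1$start[idx])]
    a <- idx[-length(idx)]; b <- idx[-1L]
    df <- data.frame(chrom1 = anchors$chrom1[a], start1 = g1$end[a],
                     end1 = g1$start[b], chrom2 = anchors$chrom2[a],
                     start2 = pmin(g2$end[a], g2$end[b]),
                     end2 = pmax(g2$start[a], g2$start[b]),
                     anchor_left = anchors$gene1[a],
                     anchor_right = anchors$gene1[b],
                     stringsAsFactors = FALSE)
    df[df$end1 > df$start1 & df$end2 > df$start2, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  rownames(out) <- NULL
  out
}

# Karlin-Altschul parameters for the ungapped +1/-2 scheme under a uniform
# base background. lambda solves sum p_i p_j exp(lambda s_ij) = 1 exactly;
# K is calibrated once by Gumbel moment matching on fixed-seed random
# alignments and cached per session.
.ka_env <- new.env(parent = emptyenv())

ka_params <- function(match = 1, mismatch = -2, p_match = 0.25) {
  key <- paste(match, mismatch, p_match)
  if (!is.null(.ka_env[[key]])) return(.ka_env[[key]])
  lambda <- uniroot(function(l) {
    p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  }, c(1e-6, 10), tol = 1e-12)$root
  # Gumbel mean of the max local score: E[S] ~ (log(K m n) + gamma)/lambda
  m <- 150L; n <- 300L; reps <- 300L
  scores <- .with_seed(193721L, vapply(seq_len(reps), function(i) {
    s1 <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = "")
    .local_align(s1, s2)$score
  }, 0))
  K <- exp(lambda * mean(scores) - 0.5772156649) / (m * n)
  out <- list(lambda = lambda, K = K)
  .ka_env[[key]] <- out
  out
}

.local_align <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .dna_submat(),
    gapOpening = 5, gapExtension = 1)
  sub <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       start = Biostrings::start(sub) - 1L,  # back to 0-based
       end = Biostrings::end(sub))
}

#' Search a syntenic block for an ELE homolog
#'
#' Locally aligns the ELE query (TSS plus 200 bp downstream on the ELE
#' strand) against the counterpart block sequence on both strands
#' (Smith-Waterman, match +1 / mismatch -2 / gap open -5 / extend -1) and
#' converts the best score to a Karlin-Altschul E-value
#' `E = K m n exp(-lambda S)`. A hit requires `E <= evalue_max`.
#'
#' @param query DNA string (the 201-bp ELE query).
#' @param block_seq DNA string of the counterpart block.
#' @param block_start 0-based genomic start of `block_seq` (for hit
#'   coordinates).
#' @param evalue_max E-value cutoff. Default 0.01.
#' @return list with `hit` (logical), `start`, `end` (0-based half-open in
#'   genome coordinates), `score`, `evalue`, `strand`.
#' @export
find_homolog <- function(query, block_seq, block_start = 0L,
                         evalue_max = 0.01) {
  if (nchar(query) == 0L || nchar(block_seq) == 0L)
    .stopf("query and block sequences must be non-empty")
  ka <- ka_params()
  fwd <- .local_align(query, block_seq)
  rev <- .local_align(.revcomp(query), block_seq)
  best <- if (rev$score > fwd$score) c(rev, strand = "-") else
    c(fwd, strand = "+")
  evalue <- ka$K * nchar(query) * nchar(block_seq) *
    exp(-ka$lambda * best$score)
  list(hit = evalue <= evalue_max,
       start = block_start + best$start, end = block_start + best$end,
       score = best$score, evalue = evalue, strand = best$strand)
}

#' Classify the homology status of one ELE against one subgenome
#'
#' @param has_block does the ELE fall in a syntenic block with the
#'   counterpart subgenome?
#' @param hit [find_homolog()] result (or NULL).
#' @param peaks counterpart-subgenome active-mark peaks (H3K4me3/H3K9ac
#'   combined interval data.frame) used to decide activity.
#' @param hit_chrom chromosome of the hit locus.
#' @return one of `"no_syntenic_block"`, `"no_homologous_sequence"`,
#'   `"homologous_sequence_inactive"`, `"homologous_ele_active"`.
#' @export
classify_homology <- function(has_block, hit, peaks, hit_chrom = NULL) {
  if (!has_block) return("no_syntenic_block")
  if (is.null(hit) || !hit$hit) return("no_homologous_sequence")
  locus <- data.frame(chrom = hit_chrom, start = hit$start, end = hit$end)
  act <- nrow(overlap_pairs(locus, peaks)) > 0L
  if (act) "homologous_ele_active" else "homologous_sequence_inactive"
}

#' Subgenome-specificity category of an ELE
#'
#' From the per-counterpart homology classes: active homolog in neither
#' other subgenome makes the ELE specific to its home subgenome, in
#' exactly one `shared_two`, in both `common`.
#'
#' @param home home subgenome label (e.g. `"A"`).
#' @param calls named character vector of homology classes, one per
#'   counterpart subgenome.
#' @return category string, e.g. `"A_specific"`, `"shared_two"`,
#'   `"common"`.
#' @export
subgenome_category <- function(home, calls) {
  if (length(calls) == 0L || any(is.na(calls)))
    .stopf("homology calls for all counterpart subgenomes are required")
  n_active <- sum(calls == "homologous_ele_active")
  if (n_active == 0L) paste0(home, "_specific")
  else if (n_active < length(calls)) "shared_two"
  else "common"
}

#' Classify all ELEs across subgenomes
#'
#' Runs the full homology pipeline: collinear anchors per subgenome pair,
#' syntenic blocks, homolog search for every ELE against every other
#' subgenome, activity classification against the counterpart's active
#' marks, and the final per-ELE subgenome category.
#'
#' @param eles data.frame with `ele_id`, `chrom`, `strand`,
#'   `dominant_pos`, `subgenome`.
#' @param gene_models_by_sub named list (per subgenome) of gene model
#'   lists.
#' @param homeologs data.frame `gene1`, `gene2`, `sub1`, `sub2` over all
#'   subgenome pairs.
#' @param seqs named `DNAStringSet` (or named character) of chromosome
#'   sequences.
#' @param peaks_by_sub named list (per subgenome) of combined active-mark
#'   peak data.frames.
#' @param evalue_max E-value cutoff. Default 0.01.
#' @param query_downstream query length downstream of the TSS. Default
#'   200.
#' @return list with `calls` (one row per ELE x counterpart) and
#'   `categories` (one row per ELE with its subgenome category).
#' @export
classify_ele_homology <- function(eles, gene_models_by_sub, homeologs,
                                  seqs, peaks_by_sub, evalue_max = 0.01,
                                  query_downstream = 200L) {
  seqs <- Biostrings::DNAStringSet(seqs)
  subs <- names(gene_models_by_sub)
  blocks <- list()
  for (s1 in subs) for (s2 in setdiff(subs, s1)) {
    hm <- homeologs[homeologs$sub1 == s1 & homeologs$sub2 == s2,
                    c("gene1", "gene2"), drop = FALSE]
    if (nrow(hm) == 0L) {
      rev_ <- homeologs[homeologs$sub1 == s2 & homeologs$sub2 == s1, ]
      hm <- data.frame(gene1 = rev_$gene2, gene2 = rev_$gene1)
    }
    anch <- collinear_anchors(gene_models_by_sub[[s1]]$genes,
                              gene_models_by_sub[[s2]]$genes, hm)
    blocks[[paste(s1, s2)]] <- build_blocks(anch,
                                            gene_models_by_sub[[s1]]$genes,
                                            gene_models_by_sub[[s2]]$genes)
  }
  calls <- list()
  for (i in seq_len(nrow(eles))) {
    home <- eles$subgenome[i]
    for (s2 in setdiff(subs, home)) {
      bl <- blocks[[paste(home, s2)]]
      inb <- which(bl$chrom1 == eles$chrom[i] &
                     bl$start1 <= eles$dominant_pos[i] &
                     bl$end1 > eles$dominant_pos[i])
      if (length(inb) == 0L) {
        calls[[length(calls) + 1L]] <- data.frame(
          ele_id = eles$ele_id[i], counterpart = s2,
          class = "no_syntenic_block", hit_start = NA_integer_,
          hit_end = NA_integer_, evalue = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      b <- bl[inb[1L], ]
      tssp <- eles$dominant_pos[i]
      chrlen <- length(seqs[[eles$chrom[i]]])
      qr <- if (identical(eles$strand[i], "-"))
        c(max(0L, tssp - query_downstream), tssp + 1L)
      else c(tssp, min(chrlen, tssp + query_downstream + 1L))
      query <- as.character(Biostrings::subseq(seqs[[eles$chrom[i]]],
                                               qr[1L] + 1L, qr[2L]))
      if (identical(eles$strand[i], "-")) query <- .revcomp(query)
      bseq <- as.character(Biostrings::subseq(seqs[[b$chrom2]],
                                              b$start2 + 1L, b$end2))
      hit <- find_homolog(query, bseq, b$start2, evalue_max)
      cls <- classify_homology(TRUE, hit, peaks_by_sub[[s2]], b$chrom2)
      calls[[length(calls) + 1L]] <- data.frame(
        ele_id = eles$ele_id[i], counterpart = s2, class = cls,
        hit_start = if (hit$hit) hit$start else NA_integer_,
        hit_end = if (hit$hit) hit$end else NA_integer_,
        evalue = hit$evalue, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  categories <- do.call(rbind, lapply(split(calls, calls$ele_id),
                                      function(df) {
    home <- eles$subgenome[match(df$ele_id[1L], eles$ele_id)]
    data.frame(ele_id = df$ele_id[1L], subgenome = home,
               category = subgenome_category(home,
                                             setNames(df$class,
                                                      df$counterpart)),
               stringsAsFactors = FALSE)
  }))
  rownames(categories) <- NULL
  list(calls = calls, categories = categories)
}
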