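# CAGE tag-cluster calling: per-sample RPM normalization, per-tissue
# distance clustering of CTSS positions, replicate-support filtering, and
# the cross-tissue merge into one unified cluster set with an expression
# matrix. Clusters wider than 10 bp are broad, all others sharp.

#' Clustering parameters
#'
#' @param max_dist maximum gap (bp) between consecutive retained CTSS
#'   positions within one cluster. Default 20.
#' @param ctss_rpm_threshold per-position pooled RPM below which a CTSS
#'   never seeds or joins a cluster. Default 0.5.
#' @param min_supporting_samples replicates that must contribute signal to
#'   a cluster for it to be kept. Default 2.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(max_dist = 20L, ctss_rpm_threshold = 0.5,
                           min_supporting_samples = 2L) {
  if (max_dist < 0L) .stopf("max_dist must be >= 0")
  if (ctss_rpm_threshold < 0) .stopf("ctss_rpm_threshold must be >= 0")
  if (min_supporting_samples < 1L)
    .stopf("min_supporting_samples must be >= 1")
  structure(list(max_dist = as.integer(max_dist),
                 ctss_rpm_threshold = ctss_rpm_threshold,
                 min_supporting_samples = as.integer(min_supporting_samples)),
            class = "cluster_params")
}

#' Reads-per-million normalization of a CTSS table
#'
#' Scales each sample's counts so they sum to one million.
#'
#' @param ctss `ctss_table`.
#' @return numeric matrix of per-sample RPM, same shape as `ctss$counts`.
#' @export
normalize_rpm <- function(ctss) {
  totals <- colSums(ctss$counts)
  zero <- which(totals == 0)
  if (length(zero) > 0L)
    .stopf("sample '%s' has zero total counts", colnames(ctss$counts)[zero[1L]])
  sweep(ctss$counts, 2L, totals / 1e6, "/")
}

#' Distance-cluster CTSS positions on one chromosome and strand
#'
#' Positions whose value reaches `ctss_rpm_threshold` are partitioned into
#' maximal runs in which consecutive retained positions are at most
#' `max_dist` bp apart. Sub-threshold positions never seed or join a
#' cluster.
#'
#' @param pos sorted integer positions (0-based).
#' @param value pooled signal (RPM) per position.
#' @param params `cluster_params`.
#' @return data.frame with `start`, `end` (half-open) per cluster.
#' @export
cluster_positions <- function(pos, value, params = cluster_params()) {
  stopifnot(length(pos) == length(value))
  if (is.unsorted(pos, strictly = TRUE))
    .stopf("positions must be sorted and unique")
  keep <- value >= params$ctss_rpm_threshold
  p <- pos[keep]
  if (length(p) == 0L)
    return(data.frame(start = integer(), end = integer()))
  new_run <- c(TRUE, diff(p) > params$max_dist)
  grp <- cumsum(new_run)
  start <- tapply(p, grp, min)
  end <- tapply(p, grp, max) + 1L
  data.frame(start = as.integer(start), end = as.integer(end),
             row.names = NULL)
}

#' Replicate-support filter for pooled tissue clusters
#'
#' A tissue-level cluster is kept iff at least `min_supporting_samples`
#' replicates each contribute at least one read at a retained CTSS position
#' inside the pooled cluster interval.
#'
#' @param clusters data.frame (`start`, `end`) of pooled clusters for one
#'   chromosome/strand.
#' @param pos retained CTSS positions underlying the clusters.
#' @param rep_counts integer matrix, one row per position in `pos`, one
#'   column per replicate of the tissue.
#' @param params `cluster_params`.
#' @return `clusters` subset with an added `n_support` column.
#' @export
filter_reproducible <- function(clusters, pos, rep_counts,
                                params = cluster_params()) {
  if (nrow(clusters) == 0L) {
    clusters$n_support <- integer()
    return(clusters)
  }
  n_support <- vapply(seq_len(nrow(clusters)), function(i) {
    inside <- pos >= clusters$start[i] & pos < clusters$end[i]
    if (!any(inside)) return(0L)
    sum(colSums(rep_counts[inside, , drop = FALSE] > 0) > 0)
  }, integer(1))
  out <- clusters[n_support >= params$min_supporting_samples, , drop = FALSE]
  out$n_support <- n_support[n_support >= params$min_supporting_samples]
  rownames(out) <- NULL
  out
}

#' Sharp/broad shape of a tag cluster
#'
#' Clusters longer than 10 bp are broad; width 10 or less is sharp.
#'
#' @param width cluster widths in bp.
#' @return character vector, `"sharp"` or `"broad"`.
#' @export
shape_class <- function(width) {
  ifelse(width > 10L, "broad", "sharp")
}

#' Call CAGE tag clusters from a CTSS table
#'
#' The full per-tissue pipeline: RPM normalization, per-tissue pooled
#' distance clustering, replicate-support filtering, and the cross-tissue
#' merge ([merge_tissues()]). Positions carrying signal that never enters a
#' kept cluster are grouped into `weak` clusters (same distance rule, no
#' threshold or support requirement); these feed the chromatin-state rescue
#' of low-confidence gene TSSs.
#'
#' @param ctss `ctss_table`.
#' @param params `cluster_params`.
#' @return object of class `tag_clusters`: list with
#'   \describe{
#'     \item{clusters}{data.frame of merged clusters: `cluster_id`, `chrom`,
#'       `start`, `end`, `strand`, `dominant_pos`, `width`, `shape`,
#'       `n_support`, `weak`.}
#'     \item{sample_rpm}{matrix cluster x sample of summed member RPM.}
#'     \item{tissue_rpm}{matrix cluster x tissue (mean over replicates).}
#'     \item{samples}{the CTSS sample sheet.}
#'   }
#' @export
cluster_ctss <- function(ctss, params = cluster_params()) {
  rpm <- normalize_rpm(ctss)
  samples <- ctss$samples
  tissues <- unique(samples$tissue)
  posdf <- ctss$positions
  key <- paste(posdf$chrom, posdf$strand)
  parts <- split(seq_len(nrow(posdf)), key)

  tissue_sets <- lapply(tissues, function(tis) {
    cols <- which(samples$tissue == tis)
    pooled <- rowMeans(rpm[, cols, drop = FALSE])
    res <- lapply(parts, function(idx) {
      p <- posdf$pos[idx]
      ord <- order(p)
      idx <- idx[ord]; p <- p[ord]
      cl <- cluster_positions(p, pooled[idx], params)
      if (nrow(cl) == 0L) return(NULL)
      keep_pos <- pooled[idx] >= params$ctss_rpm_threshold
      cl <- filter_reproducible(cl, p[keep_pos],
                                ctss$counts[idx[keep_pos], cols, drop = FALSE],
                                params)
      if (nrow(cl) == 0L) return(NULL)
      cl$chrom <- posdf$chrom[idx[1L]]
      cl$strand <- posdf$strand[idx[1L]]
      cl
    })
    res <- do.call(rbind, res)
    if (is.null(res)) res <- data.frame(start = integer(), end = integer(),
                                        n_support = integer(),
                                        chrom = character(),
                                        strand = character())
    res$tissue <- rep(tis, nrow(res))
    res
  })

  merged <- merge_tissues(tissue_sets)

  # Weak clusters: signal positions outside every kept cluster, grouped by
  # the same distance rule with no threshold/support requirement.
  pooled_all <- rowMeans(rpm)
  in_kept <- rep(FALSE, nrow(posdf))
  if (nrow(merged) > 0L) {
    hits <- overlap_pairs(
      data.frame(chrom = posdf$chrom, start = posdf$pos,
                 end = posdf$pos + 1L),
      merged)
    same_strand <- posdf$strand[hits$query] == merged$strand[hits$subject]
    in_kept[unique(hits$query[same_strand])] <- TRUE
  }
  weak_params <- cluster_params(params$max_dist, 0, 1L)
  weak <- do.call(rbind, lapply(parts, function(idx) {
    idx <- idx[!in_kept[idx] & pooled_all[idx] > 0]
    if (length(idx) == 0L) return(NULL)
    p <- posdf$pos[idx]
    ord <- order(p)
    idx <- idx[ord]; p <- p[ord]
    cl <- cluster_positions(p, pooled_all[idx], weak_params)
    cl$chrom <- posdf$chrom[idx[1L]]
    cl$strand <- posdf$strand[idx[1L]]
    cl$n_support <- vapply(seq_len(nrow(cl)), function(i) {
      inside <- p >= cl$start[i] & p < cl$end[i]
      sum(colSums(ctss$counts[idx[inside], , drop = FALSE] > 0) > 0)
    }, integer(1))
    cl
  }))
  if (!is.null(weak) && nrow(weak) > 0L) {
    weak$weak <- TRUE
    merged$weak <- rep(FALSE, nrow(merged))
    all_cl <- rbind(merged[, c("chrom", "start", "end", "strand",
                               "n_support", "weak")],
                    weak[, c("chrom", "start", "end", "strand",
                             "n_support", "weak")])
  } else {
    merged$weak <- rep(FALSE, nrow(merged))
    all_cl <- merged[, c("chrom", "start", "end", "strand", "n_support",
                         "weak")]
  }
  all_cl <- sort_intervals(all_cl)

  # Per-cluster expression and dominant position from all-sample signal.
  n <- nrow(all_cl)
  sample_rpm <- matrix(0, n, ncol(rpm), dimnames = list(NULL, colnames(rpm)))
  dominant <- integer(n)
  if (n > 0L) {
    hits <- overlap_pairs(all_cl,
                          data.frame(chrom = posdf$chrom, start = posdf$pos,
                                     end = posdf$pos + 1L))
    same <- all_cl$strand[hits$query] == posdf$strand[hits$subject]
    hits <- hits[same, , drop = FALSE]
    for (i in seq_len(n)) {
      idx <- hits$subject[hits$query == i]
      if (length(idx) == 0L) next
      sample_rpm[i, ] <- colSums(rpm[idx, , drop = FALSE])
      pooled <- rowSums(rpm[idx, , drop = FALSE])
      dominant[i] <- posdf$pos[idx[order(-pooled, posdf$pos[idx])[1L]]]
    }
  }
  tissue_rpm <- sapply(tissues, function(tis) {
    rowMeans(sample_rpm[, samples$tissue == tis, drop = FALSE])
  })
  tissue_rpm <- matrix(tissue_rpm, nrow = n,
                       dimnames = list(NULL, tissues))

  all_cl$dominant_pos <- dominant
  all_cl$width <- all_cl$end - all_cl$start
  all_cl$shape <- shape_class(all_cl$width)
  all_cl$cluster_id <- sprintf("TC%05d", seq_len(n))
  all_cl <- all_cl[, c("cluster_id", "chrom", "start", "end", "strand",
                       "dominant_pos", "width", "shape", "n_support", "weak")]
  rownames(sample_rpm) <- rownames(tissue_rpm) <- all_cl$cluster_id
  structure(list(clusters = all_cl, sample_rpm = sample_rpm,
                 tissue_rpm = tissue_rpm, samples = samples,
                 params = params),
            class = "tag_clusters")
}

#' @export
print.tag_clusters <- function(x, ...) {
  k <- x$clusters
  cat(sprintf("tag_clusters: %d clusters (%d confident, %d weak)\n",
              nrow(k), sum(!k$weak), sum(k$weak)))
  if (nrow(k) > 0L)
    cat(sprintf("  sharp/broad among confident: %d/%d\n",
                sum(!k$weak & k$shape == "sharp"),
                sum(!k$weak & k$shape == "broad")))
  invisible(x)
}

#' Merge per-tissue cluster sets into a unified set
#'
#' Same-strand clusters from different tissues overlapping by at least one
#' bp are merged into their union interval. The merge is idempotent and
#' invariant to tissue input order; `n_support` of a merged cluster is the
#' maximum over its members.
#'
#' @param tissue_sets list of data.frames (`chrom`, `start`, `end`,
#'   `strand`, `n_support`, `tissue`).
#' @return data.frame of merged clusters.
#' @export
merge_tissues <- function(tissue_sets) {
  all_df <- do.call(rbind, tissue_sets)
  if (is.null(all_df) || nrow(all_df) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_support = integer()))
  out <- lapply(split(all_df, paste(all_df$chrom, all_df$strand)),
                function(df) {
    ir <- IRanges::IRanges(df$start + 1L, df$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    data.frame(chrom = df$chrom[1L],
               start = as.integer(IRanges::start(red)) - 1L,
               end = as.integer(IRanges::end(red)),
               strand = df$strand[1L],
               n_support = as.integer(tapply(df$n_support, grp, max)),
               stringsAsFactors = FALSE)
  })
  sort_intervals(do.call(rbind, out))
}
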