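# Linking ELEs to putative target genes: candidate pairing within a 2 Mb
# window, the distance-decay regulatory-potential (RP) score, per-pair
# CAGE expression correlation, and the combined prediction rule
# (correlation > corr_min and gene RP in the top quantile). Also the tau
# tissue-specificity index used to label ELEs and genes.

#' Regulatory-potential linking parameters
#'
#' @param d0 decay distance of the RP weight `2^(-d/d0)` in bp.
#'   Default 100 kb.
#' @param window maximum ELE-gene pairing distance in bp. Default 2 Mb.
#' @param k_range_multiplier ELEs within `k_range_multiplier * d0` of the
#'   gene contribute to its RP sum. Default 20.
#' @param corr_min pairs must exceed this Pearson correlation (strictly).
#'   Default 0.5.
#' @param rp_quantile genes at or above this RP quantile (over genes with
#'   at least one contributing ELE) are eligible. Default 0.5 (top half).
#' @return object of class `rp_params`.
#' @export
rp_params <- function(d0 = 1e5, window = 2e6, k_range_multiplier = 20,
                      corr_min = 0.5, rp_quantile = 0.5) {
  if (d0 <= 0 || window <= 0) .stopf("d0 and window must be positive")
  if (corr_min < 0 || corr_min > 1) .stopf("corr_min must be in [0, 1]")
  if (rp_quantile <= 0 || rp_quantile > 1)
    .stopf("rp_quantile must be in (0, 1]")
  structure(list(d0 = d0, window = window,
                 k_range_multiplier = k_range_multiplier,
                 corr_min = corr_min, rp_quantile = rp_quantile),
            class = "rp_params")
}

#' Candidate ELE-gene pairs within the pairing window
#'
#' All (ELE, gene) pairs on the same chromosome whose point distance
#' (ELE dominant position to gene TSS) is at most `window`.
#'
#' @param eles data.frame with `ele_id`, `chrom`, `dominant_pos`.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param params `rp_params`.
#' @return data.frame `ele_id`, `gene_id`, `distance`.
#' @export
candidate_pairs <- function(eles, genes, params = rp_params()) {
  out <- lapply(intersect(unique(eles$chrom), unique(genes$chrom)),
                function(ch) {
    e <- eles[eles$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    d <- abs(outer(e$dominant_pos, g$tss, "-"))
    idx <- which(d <= params$window, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(ele_id = e$ele_id[idx[, 1L]], gene_id = g$gene_id[idx[, 2L]],
               distance = d[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ele_id = character(), gene_id = character(),
                      distance = numeric())
  out[order(out$gene_id, out$distance, out$ele_id), , drop = FALSE]
}

#' Regulatory-potential score of a gene
#'
#' `RP = sum_i 2^(-d_i / d0)` over the ELEs within
#' `k_range_multiplier * d0` of the gene; more distant ELEs contribute
#' nothing.
#'
#' @param distances non-negative distances (bp) of the gene's candidate
#'   ELEs.
#' @param params `rp_params`.
#' @return scalar RP score.
#' @export
rp_score <- function(distances, params = rp_params()) {
  if (any(distances < 0)) .stopf("distances must be non-negative")
  d <- distances[distances <= params$k_range_multiplier * params$d0]
  sum(2^(-d / params$d0))
}

#' Pearson correlation of ELE and gene expression
#'
#' Standard Pearson correlation of per-sample RPM vectors over the same
#' samples. A zero-variance vector makes the correlation undefined
#' (returned as `NA`), which downstream always fails the correlation
#' filter.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Pearson r, or `NA`.
#' @export
expression_correlation <- function(x, y) {
  if (length(x) != length(y)) .stopf("expression vectors differ in length")
  if (length(x) < 3L) .stopf("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Predict ELE target genes
#'
#' A candidate pair is a predicted target iff its correlation strictly
#' exceeds `corr_min` and its gene's RP score is at or above the RP
#' quantile threshold, where the threshold is taken over all genes with at
#' least one contributing ELE.
#'
#' @param pairs candidate pairs (`ele_id`, `gene_id`, `distance`).
#' @param ele_rpm matrix ELE x sample of RPM.
#' @param gene_rpm matrix gene x sample of RPM (same sample columns).
#' @param params `rp_params`.
#' @return object of class `target_links`: data.frame of pairs with `rp`
#'   (gene-level), `r`, `predicted`, plus attributes `rp_threshold` and
#'   `gene_rp`.
#' @export
predict_targets <- function(pairs, ele_rpm, gene_rpm,
                            params = rp_params()) {
  pairs <- pairs[order(pairs$gene_id, pairs$distance, pairs$ele_id), ,
                 drop = FALSE]
  contributing <- pairs$distance <= params$k_range_multiplier * params$d0
  gene_rp <- vapply(split(pairs$distance[contributing],
                          pairs$gene_id[contributing]),
                    rp_score, 0, params = params)
  rp_threshold <- unname(quantile(gene_rp, 1 - params$rp_quantile,
                                  type = 1L))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    e <- pairs$ele_id[i]; g <- pairs$gene_id[i]
    if (!e %in% rownames(ele_rpm) || !g %in% rownames(gene_rpm))
      return(NA_real_)
    expression_correlation(ele_rpm[e, ], gene_rpm[g, ])
  }, 0)
  rp <- unname(gene_rp[pairs$gene_id])
  rp[is.na(rp)] <- 0
  predicted <- !is.na(r) & r > params$corr_min & rp >= rp_threshold
  out <- data.frame(ele_id = pairs$ele_id, gene_id = pairs$gene_id,
                    distance = pairs$distance, rp = rp, r = r,
                    predicted = predicted, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rp_threshold") <- rp_threshold
  attr(out, "gene_rp") <- gene_rp
  class(out) <- c("target_links", "data.frame")
  out
}

#' @export
print.target_links <- function(x, ...) {
  cat(sprintf("target_links: %d candidate pairs, %d predicted (RP threshold %.4f)\n",
              nrow(x), sum(x$predicted), attr(x, "rp_threshold")))
  NextMethod()
}

#' Tissue-specificity labels from per-tissue expression
#'
#' The tau index `sum(1 - x_i / x_max) / (n - 1)` over per-tissue means.
#' Features with `tau >= tau_min` are specific to their maximal tissue,
#' expressed features below it are ubiquitous, all-zero rows are silent.
#'
#' @param tissue_means matrix feature x tissue of mean RPM (>= 2 tissues,
#'   named columns).
#' @param tau_min specificity cutoff. Default 0.8.
#' @return data.frame with `tau`, `label` (`specific`/`ubiquitous`/
#'   `silent`) and `tissue` (the argmax tissue for specific features,
#'   `NA` otherwise).
#' @export
tissue_specificity <- function(tissue_means, tau_min = 0.8) {
  tissue_means <- as.matrix(tissue_means)
  if (ncol(tissue_means) < 2L)
    .stopf("tau is undefined for a single tissue")
  if (is.null(colnames(tissue_means)))
    .stopf("tissue_means must have tissue column names")
  xmax <- apply(tissue_means, 1L, max)
  n <- ncol(tissue_means)
  tau <- ifelse(xmax > 0,
                rowSums(1 - tissue_means / ifelse(xmax > 0, xmax, 1)) / (n - 1),
                NA_real_)
  label <- ifelse(xmax == 0, "silent",
                  ifelse(tau >= tau_min, "specific", "ubiquitous"))
  top <- colnames(tissue_means)[apply(tissue_means, 1L, which.max)]
  data.frame(tau = tau, label = label,
             tissue = ifelse(label == "specific", top, NA_character_),
             row.names = rownames(tissue_means), stringsAsFactors = FALSE)
}
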