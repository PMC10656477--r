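# Hierarchical classification of merged tag clusters into gene TSSs,
# low-confidence (chromatin-state-rescued) gene TSSs, enhancer-like
# element TSSs, residual intergenic clusters and a proximal-unclassified
# remainder. The five categories form an exhaustive partition of the
# input clusters.

#' Annotation parameters
#'
#' @param gene_upstream_bp promoter window upstream of the annotated gene
#'   TSS that assigns a cluster to the gene. Default 500.
#' @param intergenic_min_dist_bp minimum distance from any gene model for a
#'   cluster to count as intergenic. Default 3000.
#' @param ele_required_marks histone marks any one of which qualifies an
#'   intergenic cluster as an ELE. Default H3K4me3, H3K9ac.
#' @return object of class `annotation_config`.
#' @export
annotation_config <- function(gene_upstream_bp = 500L,
                              intergenic_min_dist_bp = 3000L,
                              ele_required_marks = c("H3K4me3", "H3K9ac")) {
  if (gene_upstream_bp >= intergenic_min_dist_bp)
    .stopf("gene_upstream_bp must be smaller than intergenic_min_dist_bp")
  structure(list(gene_upstream_bp = as.integer(gene_upstream_bp),
                 intergenic_min_dist_bp = as.integer(intergenic_min_dist_bp),
                 ele_required_marks = ele_required_marks),
            class = "annotation_config")
}

# Strand-aware promoter window [TSS - w, TSS) on +, mirrored on -.
.promoter_windows <- function(genes, w) {
  minus <- genes$strand == "-"
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = ifelse(minus, genes$tss + 1L,
                            pmax(0L, genes$tss - w)),
             end = ifelse(minus, genes$tss + 1L + w, genes$tss),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Assign tag clusters to gene TSSs
#'
#' A cluster is a gene TSS iff it overlaps the gene's annotated 5'UTR or
#' the strand-aware window `gene_upstream_bp` upstream of the annotated
#' TSS, on the gene's strand. When several genes qualify, the gene whose
#' TSS is nearest to the cluster's dominant position wins; remaining ties
#' go to the lexically smallest gene id.
#'
#' @param clusters cluster data.frame (`chrom`, `start`, `end`, `strand`,
#'   `dominant_pos`).
#' @param gene_models list from [read_gff3_genes()].
#' @param config `annotation_config`.
#' @return character vector of assigned gene ids (`NA` where unassigned),
#'   one per cluster row.
#' @export
assign_gene_tss <- function(clusters, gene_models,
                            config = annotation_config()) {
  genes <- gene_models$genes
  assigned <- rep(NA_character_, nrow(clusters))
  if (nrow(clusters) == 0L || nrow(genes) == 0L) return(assigned)
  windows <- .promoter_windows(genes, config$gene_upstream_bp)
  windows <- windows[windows$end > windows$start, , drop = FALSE]
  targets <- rbind(windows[, c("gene_id", "chrom", "start", "end", "strand")],
                   gene_models$utr5[, c("gene_id", "chrom", "start", "end",
                                        "strand")])
  hits <- overlap_pairs(clusters, targets)
  same <- clusters$strand[hits$query] == targets$strand[hits$subject]
  hits <- hits[same, , drop = FALSE]
  if (nrow(hits) == 0L) return(assigned)
  gene_tss <- setNames(genes$tss, genes$gene_id)
  hit_gene <- targets$gene_id[hits$subject]
  hit_dist <- abs(clusters$dominant_pos[hits$query] - gene_tss[hit_gene])
  ord <- order(hits$query, hit_dist, hit_gene, method = "radix")
  first <- !duplicated(hits$query[ord])
  assigned[hits$query[ord][first]] <- hit_gene[ord][first]
  assigned
}

#' Split unassigned clusters into intergenic and proximal
#'
#' A cluster is intergenic iff its interval-to-interval distance to the
#' nearest gene model (any strand) exceeds `intergenic_min_dist_bp`;
#' otherwise it is proximal.
#'
#' @param clusters cluster data.frame.
#' @param gene_models gene model list.
#' @param config `annotation_config`.
#' @return logical vector: TRUE where intergenic.
#' @export
find_intergenic <- function(clusters, gene_models,
                            config = annotation_config()) {
  genes <- gene_models$genes
  if (nrow(genes) == 0L) return(rep(TRUE, nrow(clusters)))
  d <- config$intergenic_min_dist_bp
  # pad gene intervals by d + 1 so that a cluster with gap <= d overlaps the
  # padding while a gap of exactly d + 1 does not ("more than d" is strict)
  padded <- data.frame(chrom = genes$chrom,
                       start = pmax(0L, genes$start - d - 1L),
                       end = genes$end + d + 1L)
  hits <- overlap_pairs(clusters, padded)
  near <- rep(FALSE, nrow(clusters))
  near[unique(hits$query)] <- TRUE
  !near
}

#' Call ELE TSSs among intergenic clusters
#'
#' An intergenic cluster overlapping (>= 1 bp, any strand) at least one
#' peak of any required mark is an ELE TSS.
#'
#' @param clusters intergenic cluster data.frame.
#' @param peaks named list of peak interval data.frames, e.g.
#'   `list(H3K4me3 = ..., H3K9ac = ...)`.
#' @param config `annotation_config`.
#' @return character vector per cluster: comma-separated overlapping mark
#'   names, `NA` where none.
#' @export
call_ele_tss <- function(clusters, peaks, config = annotation_config()) {
  marks <- intersect(config$ele_required_marks, names(peaks))
  out <- rep(NA_character_, nrow(clusters))
  if (nrow(clusters) == 0L) return(out)
  for (mk in marks) {
    hits <- overlap_pairs(clusters, peaks[[mk]])
    idx <- unique(hits$query)
    out[idx] <- ifelse(is.na(out[idx]), mk, paste(out[idx], mk, sep = ","))
  }
  out
}

#' Rescue weak clusters as low-confidence gene TSSs
#'
#' A weak cluster whose dominant position falls in a bin decoded as the
#' TSS-active chromatin state, and which lies within a gene's 5'UTR,
#' upstream promoter window, or gene body (on the gene's strand), is
#' rescued as a low-confidence gene TSS of that gene.
#'
#' @param clusters weak cluster data.frame.
#' @param states data.frame of decoded bins: `chrom`, `start`, `end`,
#'   `state`.
#' @param tss_state integer index of the TSS-active state.
#' @param gene_models gene model list.
#' @param config `annotation_config`.
#' @return character vector of rescuing gene ids (`NA` where not rescued).
#' @export
rescue_lc_gene_tss <- function(clusters, states, tss_state, gene_models,
                               config = annotation_config()) {
  out <- rep(NA_character_, nrow(clusters))
  if (nrow(clusters) == 0L) return(out)
  active <- states[states$state == tss_state, , drop = FALSE]
  dompt <- data.frame(chrom = clusters$chrom, start = clusters$dominant_pos,
                      end = clusters$dominant_pos + 1L)
  in_state <- rep(FALSE, nrow(clusters))
  in_state[unique(overlap_pairs(dompt, active)$query)] <- TRUE
  if (!any(in_state)) return(out)

  genes <- gene_models$genes
  windows <- .promoter_windows(genes, config$gene_upstream_bp)
  windows <- windows[windows$end > windows$start, , drop = FALSE]
  body <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = genes$start, end = genes$end,
                     strand = genes$strand, stringsAsFactors = FALSE)
  targets <- rbind(windows[, names(body)],
                   gene_models$utr5[, names(body)], body)
  hits <- overlap_pairs(clusters, targets)
  ok <- in_state[hits$query] &
    clusters$strand[hits$query] == targets$strand[hits$subject]
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  gene_tss <- setNames(genes$tss, genes$gene_id)
  hit_gene <- targets$gene_id[hits$subject]
  hit_dist <- abs(clusters$dominant_pos[hits$query] - gene_tss[hit_gene])
  ord <- order(hits$query, hit_dist, hit_gene, method = "radix")
  first <- !duplicated(hits$query[ord])
  out[hits$query[ord][first]] <- hit_gene[ord][first]
  out
}

#' Annotate tag clusters hierarchically
#'
#' Applies the classification rules in fixed precedence: confident
#' clusters become gene TSSs (5'UTR/upstream-window rule), then intergenic
#' clusters with an active mark become ELE TSSs; weak clusters in the
#' TSS-active chromatin state around or within genes are rescued as
#' low-confidence gene TSSs; everything else is residual intergenic or
#' proximal-unclassified. Weak clusters are never called ELEs.
#'
#' @param tc `tag_clusters` object (or a cluster data.frame with a `weak`
#'   column).
#' @param gene_models gene model list.
#' @param peaks named list of mark peak data.frames.
#' @param states decoded chromatin-state bins (or NULL to skip rescue).
#' @param tss_state TSS-active state index (or NULL to skip rescue).
#' @param config `annotation_config`.
#' @return object of class `annotated_clusters`: list with `annotation`
#'   (cluster table plus `category`, `assigned_gene`, `marks`) and
#'   `counts` (named category counts, summing to the input cluster count).
#' @export
annotate_clusters <- function(tc, gene_models, peaks, states = NULL,
                              tss_state = NULL,
                              config = annotation_config()) {
  clusters <- if (inherits(tc, "tag_clusters")) tc$clusters else tc
  n <- nrow(clusters)
  category <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  marks <- rep(NA_character_, n)
  weak <- if ("weak" %in% names(clusters)) clusters$weak else rep(FALSE, n)

  # 1. confident gene TSSs
  conf <- which(!weak)
  g <- assign_gene_tss(clusters[conf, , drop = FALSE], gene_models, config)
  category[conf[!is.na(g)]] <- "gene_tss"
  gene[conf[!is.na(g)]] <- g[!is.na(g)]

  # 2. intergenic split and ELE calling (confident clusters only for ELEs)
  rest <- which(is.na(category))
  interg <- find_intergenic(clusters[rest, , drop = FALSE], gene_models,
                            config)
  ig <- rest[interg]
  mk <- call_ele_tss(clusters[ig, , drop = FALSE], peaks, config)
  is_ele <- !is.na(mk) & !weak[ig]
  category[ig[is_ele]] <- "ele_tss"
  marks[ig[is_ele]] <- mk[is_ele]

  # 3. low-confidence rescue of weak clusters near/within genes
  if (!is.null(states) && !is.null(tss_state)) {
    wk <- which(weak & is.na(category))
    rg <- rescue_lc_gene_tss(clusters[wk, , drop = FALSE], states,
                             tss_state, gene_models, config)
    category[wk[!is.na(rg)]] <- "lc_gene_tss"
    gene[wk[!is.na(rg)]] <- rg[!is.na(rg)]
  }

  # 4. residual
  category[ig][is.na(category[ig])] <- "intergenic_other"
  category[is.na(category)] <- "proximal_unclassified"

  lev <- c("gene_tss", "lc_gene_tss", "ele_tss", "intergenic_other",
           "proximal_unclassified")
  ann <- cbind(clusters,
               data.frame(category = factor(category, levels = lev),
                          assigned_gene = gene, marks = marks,
                          stringsAsFactors = FALSE))
  counts <- table(ann$category)
  structure(list(annotation = ann, counts = counts, config = config),
            class = "annotated_clusters")
}

#' @export
print.annotated_clusters <- function(x, ...) {
  cat("annotated_clusters:\n")
  print(x$counts)
  invisible(x)
}
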