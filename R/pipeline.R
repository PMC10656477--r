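# One-call orchestration of the full analysis: simulate -> cluster ->
# chromatin-state segmentation -> TSS annotation -> ELE-target linking ->
# TE enrichment and LTR dating -> subgenome homology, with a validated
# configuration, per-stage logging, and a machine-readable summary.

#' Build a pipeline run configuration
#'
#' @param outdir run directory (inputs are written under `outdir/data`).
#' @param seed global seed propagated to every stochastic stage.
#' @param sim `sim_config` for the synthetic inputs (its own seed is
#'   overridden by `seed`).
#' @param cluster `cluster_params`.
#' @param annotation `annotation_config`.
#' @param rp `rp_params`.
#' @param hmm list of HMM settings: `n_states`, `n_restarts`, `max_iter`,
#'   `tol`.
#' @param homology list: `evalue_max`, `query_downstream`.
#' @param verbose emit per-stage messages. Default TRUE.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("ele_run_"), seed = 1L,
                       sim = sim_config(),
                       cluster = cluster_params(),
                       annotation = annotation_config(),
                       rp = rp_params(),
                       hmm = list(n_states = 10L, n_restarts = 2L,
                                  max_iter = 100L, tol = 1e-3),
                       homology = list(evalue_max = 0.01,
                                       query_downstream = 200L),
                       verbose = TRUE) {
  sim$seed <- seed
  structure(list(outdir = outdir, seed = seed, sim = sim,
                 cluster = cluster, annotation = annotation, rp = rp,
                 hmm = hmm, homology = homology, verbose = verbose),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the invariants of every parameter block and returns all problems
#' found (empty character vector when valid).
#'
#' @param config `run_config`.
#' @return character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(cond, msg) if (cond) problems <<- c(problems, msg)
  add(!inherits(config, "run_config"), "not a run_config object")
  a <- config$annotation
  add(a$gene_upstream_bp >= a$intergenic_min_dist_bp,
      "gene_upstream_bp must be smaller than intergenic_min_dist_bp")
  r <- config$rp
  add(r$d0 <= 0, "d0 must be positive")
  add(r$window <= 0, "window must be positive")
  add(r$corr_min < 0 || r$corr_min > 1, "corr_min must be in [0, 1]")
  cl <- config$cluster
  add(cl$max_dist < 0, "max_dist must be >= 0")
  add(cl$ctss_rpm_threshold < 0, "ctss_rpm_threshold must be >= 0")
  h <- config$hmm
  add(is.null(h$n_states) || h$n_states < 2, "hmm n_states must be >= 2")
  add(config$homology$evalue_max <= 0, "evalue_max must be positive")
  s <- config$sim
  add(s$replicates_per_tissue < 2, "replicates_per_tissue must be >= 2")
  add(s$noise_rate < 0 || s$noise_rate > 1, "noise_rate must be in [0, 1]")
  problems
}

#' Run the full pipeline on a synthetic dataset
#'
#' Stages run in fixed order; each stage's outputs are written under the
#' run directory before the next starts, and any failure aborts naming
#' the stage. The result carries every intermediate needed for evaluation
#' against the planted truth.
#'
#' @param config `run_config`.
#' @return object of class `ele_run`: list with `sim`, `clusters`,
#'   `model`, `states`, `tss_state`, `annotation`, `eles`, `links`,
#'   `specificity`, `te_assign`, `family_enr`, `tissue_enr`, `ltr_ages`,
#'   `homology`, `summary`.
#' @export
run_all <- function(config = run_config()) {
  problems <- validate_config(config)
  if (length(problems) > 0L)
    .stopf("invalid configuration: %s", paste(problems, collapse = "; "))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  datadir <- file.path(config$outdir, "data")

  say("[simulate] seed %d", config$seed)
  sim <- stage("simulate", {
    s <- simulate_dataset(config$sim)
    write_dataset(s, datadir)
    s
  })

  say("[cluster] calling tag clusters")
  # read back from disk so the run exercises the on-disk interfaces
  tc <- stage("cluster", {
    ctss <- read_ctss(file.path(datadir, "ctss.tsv"))
    cluster_ctss(ctss, config$cluster)
  })

  say("[segment] fitting %d-state chromatin HMM", config$hmm$n_states)
  seg <- stage("segment", {
    bins <- sim$epigenome$bins
    binary <- lapply(bins$counts, binarize_tracks)
    model <- hmm_fit(binary, n_states = config$hmm$n_states,
                     seed = config$seed,
                     n_restarts = config$hmm$n_restarts,
                     max_iter = config$hmm$max_iter, tol = config$hmm$tol)
    decoded <- hmm_decode(model, binary)
    states <- bins$coords
    states$state <- unlist(decoded[unique(bins$coords$chrom)])
    list(model = model, states = states, tss_state = tss_active_state(model))
  })

  say("[annotate] hierarchical TSS classification")
  ann <- stage("annotate", {
    genes <- read_gff3_genes(file.path(datadir, "genes.gff3"))
    peaks <- list(
      H3K4me3 = read_bed(file.path(datadir, "peaks_H3K4me3.bed")),
      H3K9ac = read_bed(file.path(datadir, "peaks_H3K9ac.bed")))
    annotate_clusters(tc, genes, peaks, seg$states, seg$tss_state,
                      config$annotation)
  })
  gene_models <- read_gff3_genes(file.path(datadir, "genes.gff3"))

  say("[link] RP scoring and target prediction")
  link <- stage("link", {
    a <- ann$annotation
    eles <- a[a$category == "ele_tss", , drop = FALSE]
    eles$ele_id <- eles$cluster_id
    gene_ids <- a$assigned_gene[!is.na(a$assigned_gene)]
    gene_rpm <- rowsum(tc$sample_rpm[!is.na(a$assigned_gene), , drop = FALSE],
                       gene_ids)
    genes <- gene_models$genes
    genes <- genes[genes$gene_id %in% rownames(gene_rpm), , drop = FALSE]
    pairs <- candidate_pairs(eles, genes, config$rp)
    links <- predict_targets(pairs, tc$sample_rpm, gene_rpm, config$rp)
    spec <- tissue_specificity(tc$tissue_rpm[eles$cluster_id, , drop = FALSE])
    list(eles = eles, links = links, specificity = spec,
         gene_rpm = gene_rpm)
  })

  say("[te-enrich] TE assignment, enrichment and LTR dating")
  te <- stage("te-enrich", {
    te_table <- read_te_table(file.path(datadir, "te_table.tsv"))
    assign <- assign_te(link$eles, te_table)
    fam <- family_enrichment(assign, te_table, level = "subfamily")
    tis <- tissue_enrichment(assign, link$specificity, level = "subfamily")
    seqs <- Biostrings::readDNAStringSet(file.path(datadir, "genome.fa"))
    fl <- te_table[te_table$full_length, , drop = FALSE]
    pairs <- data.frame(
      te_id = fl$te_id,
      ltr5 = vapply(seq_len(nrow(fl)), function(i)
        as.character(Biostrings::subseq(seqs[[fl$chrom[i]]],
                                        fl$ltr5_start[i] + 1L,
                                        fl$ltr5_end[i])), ""),
      ltr3 = vapply(seq_len(nrow(fl)), function(i)
        as.character(Biostrings::subseq(seqs[[fl$chrom[i]]],
                                        fl$ltr3_start[i] + 1L,
                                        fl$ltr3_end[i])), ""),
      stringsAsFactors = FALSE)
    ages <- ltr_age(pairs)
    list(te_assign = assign, family_enr = fam, tissue_enr = tis,
         ltr_ages = ages)
  })

  say("[homology] cross-subgenome classification of %d ELEs",
      nrow(link$eles))
  hom <- stage("homology", {
    seqs <- Biostrings::readDNAStringSet(file.path(datadir, "genome.fa"))
    homeologs <- read.delim(file.path(datadir, "homeologs.tsv"),
                            stringsAsFactors = FALSE)
    subs <- .sub_labels(config$sim$n_subgenomes)
    gms <- lapply(setNames(subs, subs), function(s) {
      g <- gene_models
      keep <- g$genes$chrom == paste0("chr1", s)
      list(genes = g$genes[keep, , drop = FALSE],
           utr5 = g$utr5[g$utr5$chrom == paste0("chr1", s), , drop = FALSE],
           exons = g$exons[g$exons$chrom == paste0("chr1", s), , drop = FALSE])
    })
    k4 <- read_bed(file.path(datadir, "peaks_H3K4me3.bed"))
    k9 <- read_bed(file.path(datadir, "peaks_H3K9ac.bed"))
    act <- rbind(k4[, c("chrom", "start", "end")],
                 k9[, c("chrom", "start", "end")])
    peaks_by_sub <- lapply(setNames(subs, subs), function(s)
      act[act$chrom == paste0("chr1", s), , drop = FALSE])
    e <- link$eles
    e$subgenome <- substr(e$chrom, 5L, 5L)
    classify_ele_homology(e, gms, homeologs, seqs, peaks_by_sub,
                          evalue_max = config$homology$evalue_max,
                          query_downstream = config$homology$query_downstream)
  })

  summary <- c(
    n_clusters = nrow(ann$annotation),
    setNames(as.integer(ann$counts), names(ann$counts)),
    n_predicted_links = sum(link$links$predicted),
    top_enriched_subfamily_n = if (nrow(te$family_enr) > 0)
      te$family_enr$a[1L] else 0L)
  out <- structure(list(
    config = config, sim = sim, clusters = tc, model = seg$model,
    states = seg$states, tss_state = seg$tss_state, annotation = ann,
    eles = link$eles, links = link$links, specificity = link$specificity,
    gene_rpm = link$gene_rpm, te_assign = te$te_assign,
    family_enr = te$family_enr, tissue_enr = te$tissue_enr,
    ltr_ages = te$ltr_ages, homology = hom, summary = summary),
    class = "ele_run")
  .write_summary(out, file.path(config$outdir, "summary.tsv"))
  out
}

.write_summary <- function(run, path) {
  ann <- run$annotation$counts
  fam <- run$family_enr
  lines <- c(
    sprintf("n_clusters\t%d", nrow(run$annotation$annotation)),
    sprintf("%s\t%d", names(ann), as.integer(ann)),
    sprintf("n_eles\t%d", nrow(run$eles)),
    sprintf("n_predicted_links\t%d", sum(run$links$predicted)),
    sprintf("top_enriched_subfamily\t%s",
            if (nrow(fam) > 0) fam$group[1L] else "NA"),
    sprintf("n_full_length_ltr_dated\t%d",
            sum(!run$ltr_ages$saturated)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ele_run <- function(x, ...) {
  cat("ele_run pipeline result\n")
  cat(sprintf("  clusters: %d  (ELE TSSs: %d)\n",
              nrow(x$annotation$annotation), nrow(x$eles)))
  cat(sprintf("  predicted ELE-gene links: %d\n", sum(x$links$predicted)))
  if (nrow(x$family_enr) > 0)
    cat(sprintf("  top enriched TE subfamily: %s (q = %.3g)\n",
                x$family_enr$group[1L], x$family_enr$q[1L]))
  cat(sprintf("  subgenome categories: %s\n",
              paste(names(table(x$homology$categories$category)),
                    table(x$homology$categories$category),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
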