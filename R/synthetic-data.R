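# Seeded generator of a small multi-subgenome genome with planted ground
# truth: homoeologous gene models shared across subgenomes, TE subfamilies
# with a subgenome-specific expansion, TE-embedded and homoeologous
# ("common") enhancer-like elements with tissue-biased CAGE output,
# full-length LTR elements with divergence-dated LTR pairs, epigenomic
# peak and bin tracks, and per-cytosine methylation. Every downstream
# stage of the pipeline is testable against the planted truth with no
# external data.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study system: three 2-Mb subgenomes
#' (A/B/D) with shared gene order, one Gypsy subfamily (RLG_famc7.3)
#' expanded only in subgenome A and hosting spike-specific ELEs at its
#' copies' 5' edges, a smaller root-biased Copia subfamily, and a set of
#' homoeologous non-TE ELEs present and active in all subgenomes.
#'
#' @param n_subgenomes 2 or 3 subgenomes (labels A, B, D). Default 3.
#' @param chrom_length_bp chromosome length per subgenome. Default 2e6.
#' @param n_genes genes per subgenome. Default 60.
#' @param n_te_per_subfamily named list: subfamily -> integer vector of
#'   per-subgenome copy numbers.
#' @param n_planted_eles homoeologous non-TE ELE groups, each instantiated
#'   once per subgenome. Default 5.
#' @param tissue_labels tissues profiled. Default embryo, seedling, spike,
#'   root.
#' @param replicates_per_tissue CAGE replicates per tissue (>= 2).
#' @param ele_tissue_bias named list: subfamily -> tissue its ELEs are
#'   restricted to.
#' @param te_ele_fraction named numeric: fraction of each biased
#'   subfamily's copies hosting an ELE (deterministic rounding per
#'   subgenome).
#' @param ltr_divergence_range per-site substitution fraction interval for
#'   5'/3' LTR pairs of full-length elements.
#' @param noise_rate background CTSS rate per bp per strand per sample.
#' @param frac_sharp fraction of gene TSSs with sharp shape.
#' @param frac_weak fraction of genes emitting only single-replicate weak
#'   signal (rescue candidates).
#' @param frac_silent fraction of unexpressed genes.
#' @param collinear_fraction fraction of homoeolog pairs left collinear.
#' @param gene_mean expected CAGE tags per sample at an expressed gene TSS.
#' @param ele_mean expected CAGE tags per strand per sample at an active
#'   ELE edge.
#' @param seed master seed; all outputs are pure functions of the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subgenomes = 3L,
                       chrom_length_bp = 2e6,
                       n_genes = 60L,
                       n_te_per_subfamily = list(
                         RLG_famc7.3 = c(40L, 2L, 2L),
                         RLG_famc7.1 = c(8L, 8L, 8L),
                         RLC_famc1.1 = c(8L, 8L, 8L),
                         DTC_famc2.1 = c(8L, 8L, 8L)),
                       n_planted_eles = 5L,
                       tissue_labels = c("embryo", "seedling", "spike",
                                         "root"),
                       replicates_per_tissue = 2L,
                       ele_tissue_bias = list(RLG_famc7.3 = "spike",
                                              RLC_famc1.1 = "root"),
                       te_ele_fraction = c(RLG_famc7.3 = 0.6,
                                           RLC_famc1.1 = 0.25),
                       ltr_divergence_range = c(0.01, 0.06),
                       noise_rate = 1e-5,
                       frac_sharp = 0.7,
                       frac_weak = 0.08,
                       frac_silent = 0.1,
                       collinear_fraction = 0.9,
                       gene_mean = 60,
                       ele_mean = 30,
                       seed = 1L) {
  if (replicates_per_tissue < 2L)
    .stopf("replicates_per_tissue must be >= 2 (replicate-support filter)")
  fracs <- c(noise_rate = noise_rate, frac_sharp = frac_sharp,
             frac_weak = frac_weak,
             frac_silent = frac_silent,
             collinear_fraction = collinear_fraction,
             ltr_divergence_range)
  if (any(fracs < 0) || any(fracs > 1))
    .stopf("all rates and fractions must lie in [0, 1]")
  if (!all(vapply(n_te_per_subfamily, length, 0L) == n_subgenomes))
    .stopf("n_te_per_subfamily entries must have one count per subgenome")
  cfg <- as.list(environment())
  cfg$fracs <- NULL
  structure(cfg, class = "sim_config")
}

.sub_labels <- function(n) c("A", "B", "D")[seq_len(n)]

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Kimura-2P substitution process at pairwise divergence d with a 2:1
# transition:transversion ratio (alpha = 4 beta): exact finite-time
# transition/transversion probabilities.
.k2p_probs <- function(d) {
  b <- d / 6; a <- 4 * d / 6
  P <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
  Q <- 0.5 - 0.5 * exp(-4 * b)
  c(P = P, Q = Q)
}

.mutate_k2p <- function(seq, d) {
  if (d <= 0) return(seq)
  pq <- .k2p_probs(d)
  chars <- strsplit(seq, "")[[1L]]
  u <- runif(length(chars))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  ts <- u < pq["P"]
  tv <- !ts & u < pq["P"] + pq["Q"]
  chars[ts] <- ts_map[chars[ts]]
  if (any(tv)) {
    pick <- runif(sum(tv)) < 0.5
    chars[tv] <- vapply(seq_len(sum(tv)), function(i)
      tv_map[[chars[tv][i]]][if (pick[i]) 1L else 2L], "")
  }
  paste(chars, collapse = "")
}

#' Simulate a diverged 5'/3' LTR pair
#'
#' Draws a random ancestral LTR and substitutes the 3' copy at pairwise
#' divergence `divergence` under the K2P-symmetric process (ts:tv 2:1).
#'
#' @param length LTR length in bp.
#' @param divergence expected substitutions per site between the copies.
#' @param seed RNG seed.
#' @return list with `ltr5`, `ltr3`.
#' @export
simulate_ltr_pair <- function(length = 300L, divergence = 0.02, seed = 1L) {
  .with_seed(seed, {
    anc <- .rand_dna(length)
    list(ltr5 = anc, ltr3 = .mutate_k2p(anc, divergence))
  })
}

# ---- genome construction ---------------------------------------------------

#' Generate the synthetic genome
#'
#' Builds sequences, gene models, the TE table (with full-length LTR
#' coordinates and planted divergences), the homoeolog map and the ground
#' truth (planted gene TSSs, ELEs with hosts/tissues/targets, LTR ages).
#'
#' @param config `sim_config`.
#' @return list with `seqs` (DNAStringSet), `gene_models`, `te_table`,
#'   `homeologs`, `truth`, `config`.
#' @export
generate_genome <- function(config = sim_config()) {
  seeds <- .sub_seeds(config$seed, 6L)
  subs <- .sub_labels(config$n_subgenomes)
  chroms <- paste0("chr1", subs)
  len <- as.integer(config$chrom_length_bp)
  tissues <- config$tissue_labels

  # genes: identical coordinates across subgenomes (homoeologous order)
  ng <- config$n_genes
  spacing <- floor(len / (ng + 1))
  gene_len <- 3000L
  if (spacing < gene_len + 9000L)
    .stopf("chromosome too short for %d genes", ng)
  tss0 <- as.integer(seq_len(ng) * spacing)
  strand <- rep(c("+", "-"), length.out = ng)

  gene_rows <- utr_rows <- exon_rows <- list()
  for (s in seq_along(subs)) {
    for (i in seq_len(ng)) {
      gid <- sprintf("gene%s%03d", subs[s], i)
      if (strand[i] == "+") {
        gstart <- tss0[i]; gend <- tss0[i] + gene_len
        ex <- data.frame(start = c(gstart, gstart + 1500L),
                         end = c(gstart + 500L, gend))
        u5 <- data.frame(start = gstart, end = gstart + 200L)
      } else {
        gend <- tss0[i] + 1L; gstart <- gend - gene_len
        ex <- data.frame(start = c(gstart, gend - 500L),
                         end = c(gstart + 1500L, gend))
        u5 <- data.frame(start = gend - 200L, end = gend)
      }
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(gene_id = gid, chrom = chroms[s], start = gstart,
                   end = gend, strand = strand[i], tss = tss0[i],
                   stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(gene_id = gid, chrom = chroms[s], start = ex$start,
                   end = ex$end, strand = strand[i], stringsAsFactors = FALSE)
      utr_rows[[length(utr_rows) + 1L]] <-
        data.frame(gene_id = gid, chrom = chroms[s], start = u5$start,
                   end = u5$end, strand = strand[i], stringsAsFactors = FALSE)
    }
  }
  gene_models <- list(genes = do.call(rbind, gene_rows),
                      utr5 = do.call(rbind, utr_rows),
                      exons = do.call(rbind, exon_rows))

  # homoeolog map: identity pairing with a seeded fraction broken by a
  # local swap (exercises the collinearity chaining)
  homeologs <- .with_seed(seeds[1L], {
    n_break <- round((1 - config$collinear_fraction) * ng)
    broken <- if (n_break > 0) sort(sample(2:(ng - 1L), n_break)) else integer()
    perm <- seq_len(ng)
    for (b in broken) {  # swap with the neighbour: both pairs non-collinear
      tmp <- perm[b]; perm[b] <- perm[b - 1L]; perm[b - 1L] <- tmp
    }
    out <- list()
    for (s1 in seq_along(subs)) for (s2 in seq_along(subs)) {
      if (s1 >= s2) next
      out[[length(out) + 1L]] <- data.frame(
        gene1 = sprintf("gene%s%03d", subs[s1], seq_len(ng)),
        gene2 = sprintf("gene%s%03d", subs[s2], perm),
        sub1 = subs[s1], sub2 = subs[s2], stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  # candidate cells for TEs and non-TE ELEs inside intergenic gaps, at
  # least 3.5 kb from any gene so planted ELEs are unambiguously intergenic
  margin <- 3500L
  te_len <- 3000L
  cell_w <- te_len + 400L
  g1 <- gene_models$genes[gene_models$genes$chrom == chroms[1L], ]
  g1 <- g1[order(g1$start), ]
  gap_start <- c(0L, g1$end)
  gap_end <- c(g1$start, len)
  cells <- list()
  for (k in seq_along(gap_start)) {
    lo <- gap_start[k] + margin
    hi <- gap_end[k] - margin
    ncell <- max(0L, (hi - lo) %/% cell_w)
    if (ncell > 0L)
      cells[[length(cells) + 1L]] <-
        data.frame(start = lo + (seq_len(ncell) - 1L) * cell_w + 200L)
  }
  cells <- do.call(rbind, cells)$start  # identical layout per subgenome

  sfam <- names(config$n_te_per_subfamily)
  n_common <- config$n_planted_eles
  if (length(cells) < max(vapply(seq_along(subs), function(s)
        sum(vapply(config$n_te_per_subfamily, `[`, 0L, s)), 0)) + n_common)
    .stopf("chromosome too short to place requested TEs and ELEs")

  # subfamily consensus sequences (LTR superfamilies get terminal repeats)
  ltr_len <- 300L
  consensus <- .with_seed(seeds[2L], {
    lapply(setNames(sfam, sfam), function(sf) {
      if (startsWith(sf, "RL")) {
        ltr <- .rand_dna(ltr_len)
        paste0(ltr, .rand_dna(te_len - 2L * ltr_len), ltr)
      } else .rand_dna(te_len)
    })
  })

  # common (homoeologous, non-TE) ELE cores: same cell in every subgenome
  common <- .with_seed(seeds[3L], {
    cell_idx <- sample(seq_along(cells), n_common)
    data.frame(group = seq_len(n_common), cell = cells[cell_idx],
               core = vapply(seq_len(n_common), function(i) .rand_dna(600L),
                             ""))
  })
  cells_free <- setdiff(cells, common$cell)

  # TE placement, copy mutation and LTR divergence, per subgenome
  te_rows <- list()
  ltr_truth <- list()
  .with_seed(seeds[4L], {
    for (s in seq_along(subs)) {
      counts <- vapply(config$n_te_per_subfamily, `[`, 0L, s)
      total <- sum(counts)
      slot <- sample(cells_free, total)
      k <- 0L
      for (sf in sfam) {
        for (j in seq_len(counts[[sf]])) {
          k <- k + 1L
          st <- slot[k]
          full <- startsWith(sf, "RL")
          div <- if (full)
            runif(1, config$ltr_divergence_range[1L],
                  config$ltr_divergence_range[2L]) else NA_real_
          te_id <- sprintf("TE_%s_%s_%03d", subs[s], sf, j)
          seq_copy <- .mutate_k2p(consensus[[sf]], 0.02)
          if (full) {
            ltr5 <- substr(seq_copy, 1L, ltr_len)
            ltr3 <- .mutate_k2p(ltr5, div)
            seq_copy <- paste0(ltr5,
                               substr(seq_copy, ltr_len + 1L,
                                      te_len - ltr_len), ltr3)
            ltr_truth[[length(ltr_truth) + 1L]] <-
              data.frame(te_id = te_id, divergence = div,
                         age_generations = div / (2 * 1.3e-8),
                         stringsAsFactors = FALSE)
          }
          te_rows[[length(te_rows) + 1L]] <- data.frame(
            te_id = te_id, chrom = chroms[s], start = st,
            end = st + te_len, strand = "+",
            superfamily = sub("_.*", "", sf),
            family = sub("\\.[0-9]+$", "", sf), subfamily = sf,
            full_length = full,
            ltr5_start = if (full) st else NA_integer_,
            ltr5_end = if (full) st + ltr_len else NA_integer_,
            ltr3_start = if (full) st + te_len - ltr_len else NA_integer_,
            ltr3_end = if (full) st + te_len else NA_integer_,
            seq = seq_copy, stringsAsFactors = FALSE)
        }
      }
    }
  })
  te_table <- do.call(rbind, te_rows)
  ltr_truth <- do.call(rbind, ltr_truth)

  # plant ELEs: TE-hosted (subfamily-biased tissues) and common groups
  ele_rows <- list()
  .with_seed(seeds[5L], {
    for (sf in names(config$ele_tissue_bias)) {
      tis <- config$ele_tissue_bias[[sf]]
      frac <- config$te_ele_fraction[[sf]]
      for (s in seq_along(subs)) {
        copies <- te_table[te_table$subfamily == sf &
                             te_table$chrom == chroms[s], , drop = FALSE]
        n_host <- round(frac * nrow(copies))
        if (n_host == 0L) next
        host <- copies[sample(nrow(copies), n_host), , drop = FALSE]
        for (i in seq_len(nrow(host))) {
          st <- host$start[i] + 50L
          ele_rows[[length(ele_rows) + 1L]] <- data.frame(
            truth_id = sprintf("ele_%s_%d", sf, length(ele_rows) + 1L),
            chrom = host$chrom[i], subgenome = subs[s], start = st,
            end = st + 10L, host_te = host$te_id[i], tissues = tis,
            common_group = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
    for (i in seq_len(nrow(common))) {
      for (s in seq_along(subs)) {
        st <- common$cell[i] + 100L
        ele_rows[[length(ele_rows) + 1L]] <- data.frame(
          truth_id = sprintf("ele_common%d_%s", common$group[i], subs[s]),
          chrom = chroms[s], subgenome = subs[s], start = st,
          end = st + 10L, host_te = NA_character_,
          tissues = paste(tissues, collapse = ","),
          common_group = common$group[i], stringsAsFactors = FALSE)
      }
    }
  })
  eles <- do.call(rbind, ele_rows)

  # gene classes, expression profiles and ELE target assignment
  truth_genes <- .with_seed(seeds[6L], {
    g <- gene_models$genes
    g$subgenome <- substr(g$chrom, 5L, 5L)
    g$shape <- sample(c("sharp", "broad"), nrow(g), replace = TRUE,
                      prob = c(config$frac_sharp, 1 - config$frac_sharp))
    cls <- sample(c("active", "weak", "silent"), nrow(g), replace = TRUE,
                  prob = c(1 - config$frac_weak - config$frac_silent,
                           config$frac_weak, config$frac_silent))
    g$class <- cls
    expr <- matrix(rep(ifelse(cls == "active", config$gene_mean, 0),
                       length(tissues)),
                   ncol = length(tissues),
                   dimnames = list(g$gene_id, tissues))
    g$broad_width <- sample(20:60, nrow(g), replace = TRUE)

    # common-group ELE profiles: a permuted two-fold ladder, so the pair
    # correlation with the target gene is signal- rather than
    # noise-driven while tau stays below the specificity cutoff
    ladder <- 8 * 2^(seq_along(tissues) - 1L)
    grp_prof <- lapply(seq_len(n_common), function(i) sample(ladder))
    ele_prof <- matrix(0, nrow(eles), length(tissues),
                       dimnames = list(eles$truth_id, tissues))
    for (i in seq_len(nrow(eles))) {
      if (!is.na(eles$common_group[i])) {
        ele_prof[i, ] <- grp_prof[[eles$common_group[i]]]
      } else {
        ele_prof[i, eles$tissues[i]] <- config$ele_mean
      }
    }

    # targets: nearest active gene on the same chromosome not yet taken
    taken <- character()
    target <- rep(NA_character_, nrow(eles))
    for (i in seq_len(nrow(eles))) {
      cand <- g[g$chrom == eles$chrom[i] & g$class == "active" &
                  !(g$gene_id %in% taken), , drop = FALSE]
      if (nrow(cand) == 0L) next
      j <- which.min(abs(cand$tss - eles$start[i]))
      target[i] <- cand$gene_id[j]
      taken <- c(taken, cand$gene_id[j])
      if (!is.na(eles$common_group[i])) {
        expr[cand$gene_id[j], ] <- 1.5 * ele_prof[i, ]
      } else {
        prof <- rep(0.1 * config$gene_mean, length(tissues))
        prof[tissues == eles$tissues[i]] <- config$gene_mean
        expr[cand$gene_id[j], ] <- prof
      }
    }
    list(genes = g, expr = expr, ele_expr = ele_prof, target = target)
  })
  eles$target_gene <- truth_genes$target

  # assemble sequences: random background, then TE copies and ELE cores
  seq_sets <- .with_seed(seeds[2L] + 1L, {
    lapply(seq_along(subs), function(s) {
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      te_s <- te_table[te_table$chrom == chroms[s], , drop = FALSE]
      for (i in seq_len(nrow(te_s)))
        chars[(te_s$start[i] + 1L):te_s$end[i]] <-
          strsplit(te_s$seq[i], "")[[1L]]
      for (i in seq_len(nrow(common)))
        chars[(common$cell[i] + 1L):(common$cell[i] + 600L)] <-
          strsplit(common$core[i], "")[[1L]]
      paste(chars, collapse = "")
    })
  })
  seqs <- Biostrings::DNAStringSet(setNames(unlist(seq_sets), chroms))

  truth <- list(genes = truth_genes$genes, gene_expr = truth_genes$expr,
                eles = eles, ele_expr = truth_genes$ele_expr,
                ltr = ltr_truth)
  te_table$seq <- NULL
  list(seqs = seqs, gene_models = gene_models, te_table = te_table,
       homeologs = homeologs, truth = truth, config = config)
}

# ---- CAGE signal -----------------------------------------------------------

#' Simulate per-sample CTSS counts
#'
#' Gene TSSs emit tags from a peaked positional distribution (sharp: at
#' least 90\% of tags within 10 bp; broad: spread over the gene's drawn
#' width), planted ELEs emit bidirectionally from their 5' edge in their
#' active tissues only, weak genes emit a two-tag single-replicate signal,
#' and background positions emit Poisson noise. Replicates are independent
#' draws sharing tissue-level means.
#'
#' @param genome output of [generate_genome()].
#' @param seed RNG seed (defaults to the config seed + 1).
#' @return `ctss_table`.
#' @export
simulate_ctss <- function(genome, seed = NULL) {
  config <- genome$config
  if (is.null(seed)) seed <- config$seed + 1L
  tissues <- config$tissue_labels
  reps <- config$replicates_per_tissue
  samples <- as.vector(outer(tissues, seq_len(reps),
                             function(t, r) paste0(t, "_rep", r)))
  truth <- genome$truth
  genes <- truth$genes
  chrom_len <- config$chrom_length_bp

  .with_seed(seed, {
    acc <- new.env(parent = emptyenv())
    add <- function(chrom, pos, strand, sample, n) {
      keep <- n > 0
      if (!any(keep)) return()
      key <- paste0(chrom, ":", pos[keep], ":", strand)
      for (i in seq_along(key)) {
        cur <- acc[[key[i]]]
        if (is.null(cur)) cur <- setNames(numeric(length(samples)), samples)
        cur[sample] <- cur[sample] + n[keep][i]
        acc[[key[i]]] <- cur
      }
    }
    sharp_w <- c(30, 15, 10, 8, 7, 6, 5, 5, 4, 3)   # all mass within 10 bp
    for (i in seq_len(nrow(genes))) {
      cls <- genes$class[i]
      if (cls == "silent") next
      dirn <- if (genes$strand[i] == "+") 1L else -1L
      if (cls == "weak") {
        # two tags at the TSS in a single replicate of one tissue
        smp <- paste0(tissues[1L], "_rep1")
        add(genes$chrom[i], genes$tss[i] + dirn * c(0L, 2L),
            genes$strand[i], smp, c(2L, 2L))
        next
      }
      w <- if (genes$shape[i] == "sharp") sharp_w
      else rep(1, genes$broad_width[i])
      offs <- dirn * (seq_along(w) - 1L)
      for (tis in tissues) {
        mu <- truth$gene_expr[genes$gene_id[i], tis]
        if (mu == 0) next
        for (r in seq_len(reps)) {
          tot <- rpois(1L, mu)
          if (tot == 0L) next
          n <- as.vector(rmultinom(1L, tot, w))
          add(genes$chrom[i], genes$tss[i] + offs, genes$strand[i],
              paste0(tis, "_rep", r), n)
        }
      }
    }
    ele_w <- c(12, 8, 5, 3, 2)
    for (i in seq_len(nrow(truth$eles))) {
      e <- truth$eles[i, ]
      for (tis in tissues) {
        mu <- truth$ele_expr[e$truth_id, tis]
        if (mu == 0) next
        for (r in seq_len(reps)) {
          for (strand in c("+", "-")) {
            tot <- rpois(1L, mu)
            if (tot == 0L) next
            n <- as.vector(rmultinom(1L, tot, ele_w))
            add(e$chrom, e$start + seq_along(ele_w) - 1L, strand,
                paste0(tis, "_rep", r), n)
          }
        }
      }
    }
    chroms <- names(genome$seqs)
    for (ch in chroms) {
      for (smp in samples) {
        for (strand in c("+", "-")) {
          k <- rpois(1L, config$noise_rate * chrom_len)
          if (k == 0L) next
          add(ch, sample.int(chrom_len, k) - 1L, strand, smp,
              rep(1L, k))
        }
      }
    }
    keys <- ls(acc)
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    counts <- do.call(rbind, lapply(keys, function(k) acc[[k]]))
    storage.mode(counts) <- "integer"
    ctss_table(data.frame(chrom = parts[, 1L],
                          pos = as.integer(parts[, 2L]),
                          strand = parts[, 3L], stringsAsFactors = FALSE),
               counts)
  })
}

# ---- epigenome -------------------------------------------------------------

#' Simulate epigenomic peaks, HMM bin tracks and methylation
#'
#' Active gene promoters and active ELEs receive H3K4me3 and H3K9ac
#' peaks; silent-gene bodies receive sparse H3K27me3; the per-bin count
#' matrix carries promoter (CAGE/H3K4me3/H3K9ac/open/nascentRNA), gene
#' body (H3K36me3/nascentRNA) and ELE signal over Poisson background; TE
#' bodies are hyper-methylated in CG/CHG except hypo-methylated windows
#' around planted ELEs.
#'
#' @param genome output of [generate_genome()].
#' @param bin_size HMM bin width in bp. Default 500.
#' @param seed RNG seed (defaults to the config seed + 2).
#' @return list with `peaks` (named list of BED-style data.frames),
#'   `bins` (`bin_coords` data.frame and per-chromosome count matrices),
#'   `methylation` (data.frame).
#' @export
simulate_epigenome <- function(genome, bin_size = 500L, seed = NULL) {
  config <- genome$config
  if (is.null(seed)) seed <- config$seed + 2L
  truth <- genome$truth
  genes <- truth$genes
  chroms <- names(genome$seqs)
  len <- config$chrom_length_bp

  expressed <- genes$class %in% c("active", "weak")
  prom <- data.frame(chrom = genes$chrom[expressed],
                     start = pmax(0L, genes$tss[expressed] - 200L),
                     end = genes$tss[expressed] + 400L,
                     name = genes$gene_id[expressed])
  ele <- truth$eles
  ele_pk <- data.frame(chrom = ele$chrom,
                       start = pmax(0L, ele$start - 200L),
                       end = ele$start + 400L, name = ele$truth_id)
  silent <- genes$class == "silent"
  k27 <- data.frame(chrom = genes$chrom[silent], start = genes$start[silent],
                    end = genes$end[silent], name = genes$gene_id[silent])
  peaks <- list(H3K4me3 = rbind(prom, ele_pk),
                H3K9ac = rbind(prom, ele_pk),
                H3K27me3 = k27)
  peaks <- lapply(peaks, sort_intervals)

  .with_seed(seed, {
    tracks <- c("CAGE", "H3K4me3", "H3K9ac", "H3K36me3", "open",
                "nascentRNA")
    nbin <- len %/% bin_size
    bin_mats <- list()
    coords <- list()
    for (ch in chroms) {
      M <- matrix(rpois(nbin * length(tracks), 1), nbin,
                  dimnames = list(NULL, tracks))
      mark <- function(start, end, cols, lam = 25) {
        b1 <- pmax(0L, start) %/% bin_size + 1L
        b2 <- pmin(len - 1L, end - 1L) %/% bin_size + 1L
        for (i in seq_along(b1)) {
          rows <- b1[i]:b2[i]
          M[rows, cols] <<- M[rows, cols] +
            matrix(rpois(length(rows) * length(cols), lam), length(rows))
        }
      }
      gs <- genes[genes$chrom == ch & expressed, , drop = FALSE]
      mark(gs$tss - 250L, gs$tss + 250L,
           c("CAGE", "H3K4me3", "H3K9ac", "open", "nascentRNA"))
      mark(gs$start, gs$end, c("H3K36me3", "nascentRNA"), lam = 12)
      es <- ele[ele$chrom == ch, , drop = FALSE]
      mark(es$start - 100L, es$start + 300L,
           c("CAGE", "H3K4me3", "H3K9ac", "open"))
      bin_mats[[ch]] <- M
      coords[[ch]] <- data.frame(chrom = ch,
                                 start = (seq_len(nbin) - 1L) * bin_size,
                                 end = seq_len(nbin) * bin_size)
    }
    bins <- list(coords = do.call(rbind, coords), counts = bin_mats,
                 bin_size = bin_size)

    te <- genome$te_table
    hypo <- data.frame(chrom = ele$chrom[!is.na(ele$host_te)],
                       start = ele$start[!is.na(ele$host_te)] - 300L,
                       end = ele$start[!is.na(ele$host_te)] + 500L)
    meth <- list()
    for (i in seq_len(nrow(te))) {
      pos <- seq(te$start[i], te$end[i] - 1L, by = 13L)
      ctx <- rep(c("CG", "CHG"), length.out = length(pos))
      cov <- rpois(length(pos), 8)
      level <- rep(0.9, length(pos))
      if (nrow(hypo) > 0L) {
        inh <- rep(FALSE, length(pos))
        hh <- hypo[hypo$chrom == te$chrom[i], , drop = FALSE]
        for (j in seq_len(nrow(hh)))
          inh <- inh | (pos >= hh$start[j] & pos < hh$end[j])
        level[inh] <- 0.1
      }
      mC <- rbinom(length(pos), cov, level)
      meth[[i]] <- data.frame(chrom = te$chrom[i], pos = pos, strand = "+",
                              context = ctx, methylated_reads = mC,
                              total_reads = cov, stringsAsFactors = FALSE)
    }
    methylation <- if (length(meth) > 0L) do.call(rbind, meth)
    else data.frame(chrom = character(), pos = integer(),
                    strand = character(), context = character(),
                    methylated_reads = integer(), total_reads = integer())
    list(peaks = peaks, bins = bins, methylation = methylation)
  })
}

#' Simulate a complete dataset
#'
#' @param config `sim_config`.
#' @return list with `genome`, `ctss`, `epigenome`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- generate_genome(config)
  list(genome = genome,
       ctss = simulate_ctss(genome),
       epigenome = simulate_epigenome(genome))
}

#' Write a simulated dataset to disk
#'
#' Emits every format the downstream stages consume: FASTA, GFF3, CTSS
#' table, peak BEDs, the HMM bin count matrix, TE table, methylation
#' table, homoeolog map and the ground-truth tables.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(sim$genome$seqs, p("genome.fa"))
  write_gff3_genes(sim$genome$gene_models, p("genes.gff3"))
  write_ctss(sim$ctss, p("ctss.tsv"))
  write_te_table(sim$genome$te_table, p("te_table.tsv"))
  for (mk in names(sim$epigenome$peaks))
    write_bed(sim$epigenome$peaks[[mk]], p(paste0("peaks_", mk, ".bed")))
  bins <- sim$epigenome$bins
  bin_df <- cbind(bins$coords,
                  do.call(rbind, bins$counts[unique(bins$coords$chrom)]))
  write.table(bin_df, p("hmm_bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$epigenome$methylation, p("methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genome$homeologs, p("homeologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genome$truth$eles, p("truth_eles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- sim$genome$truth$genes
  write.table(g, p("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$genome$truth$ltr))
    write.table(sim$genome$truth$ltr, p("truth_ltr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  files <- list.files(outdir, full.names = TRUE)
  invisible(setNames(files, basename(files)))
}
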