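# Generator determinism, planted-truth consistency, and signal behaviour.

small_cfg <- function(seed = 5L, ...) {
  sim_config(n_genes = 20L, chrom_length_bp = 8e5,
             n_te_per_subfamily = list(RLG_famc7.3 = c(12L, 1L, 1L),
                                       RLC_famc1.1 = c(4L, 4L, 4L)),
             ele_tissue_bias = list(RLG_famc7.3 = "spike",
                                    RLC_famc1.1 = "root"),
             te_ele_fraction = c(RLG_famc7.3 = 0.5, RLC_famc1.1 = 0.25),
             n_planted_eles = 3L, seed = seed, ...)
}

test_that("generation is a pure function of the config seed", {
  g1 <- generate_genome(small_cfg())
  g2 <- generate_genome(small_cfg())
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  expect_identical(g1$te_table, g2$te_table)
  expect_identical(g1$truth$eles, g2$truth$eles)
  c1 <- simulate_ctss(g1)
  c2 <- simulate_ctss(g2)
  expect_identical(c1$counts, c2$counts)
  e1 <- simulate_epigenome(g1)
  e2 <- simulate_epigenome(g2)
  expect_identical(e1$peaks, e2$peaks)
  expect_identical(e1$bins$counts, e2$bins$counts)

  g3 <- generate_genome(small_cfg(seed = 6L))
  expect_false(identical(as.character(g1$seqs), as.character(g3$seqs)))
})

test_that("planted truth is internally consistent", {
  g <- generate_genome(small_cfg())
  eles <- g$truth$eles
  te <- g$te_table
  hosted <- eles[!is.na(eles$host_te), ]
  host <- te[match(hosted$host_te, te$te_id), ]
  expect_true(all(hosted$start >= host$start & hosted$end <= host$end))
  expect_true(all(nchar(eles$tissues) > 0L))
  with_target <- eles[!is.na(eles$target_gene), ]
  tss <- g$gene_models$genes$tss[match(with_target$target_gene,
                                       g$gene_models$genes$gene_id)]
  expect_true(all(abs(tss - with_target$start) <= 2e6))
  # the expanded subfamily is expanded only in subgenome A
  cnt <- table(te$subfamily, substr(te$chrom, 5L, 5L))
  expect_gte(cnt["RLG_famc7.3", "A"], 10 * cnt["RLG_famc7.3", "B"])
})

test_that("full-length LTR pairs carry the planted divergence structure", {
  cfg <- small_cfg()
  cfg$ltr_divergence_range <- c(0, 0)
  g <- generate_genome(cfg)
  fl <- g$te_table[g$te_table$full_length, ][1:5, ]
  for (i in seq_len(nrow(fl))) {
    s <- g$seqs[[fl$chrom[i]]]
    l5 <- as.character(Biostrings::subseq(s, fl$ltr5_start[i] + 1L,
                                          fl$ltr5_end[i]))
    l3 <- as.character(Biostrings::subseq(s, fl$ltr3_start[i] + 1L,
                                          fl$ltr3_end[i]))
    expect_identical(l5, l3)
  }
})

test_that("CTSS output respects tissue restriction and mean scaling", {
  g <- generate_genome(small_cfg())
  ct <- simulate_ctss(g)
  spike_eles <- g$truth$eles[g$truth$eles$tissues == "spike", ]
  e <- spike_eles[1L, ]
  inside <- ct$positions$chrom == e$chrom & ct$positions$pos >= e$start &
    ct$positions$pos < e$end
  spike_cols <- ct$samples$tissue == "spike"
  expect_gt(sum(ct$counts[inside, spike_cols]), 0)
  expect_equal(sum(ct$counts[inside, !spike_cols]), 0)

  # doubling a tissue mean doubles expected counts (law of large numbers)
  cfg2 <- small_cfg(); cfg2$ele_mean <- 2 * cfg2$ele_mean
  g2 <- generate_genome(cfg2)
  e2 <- g2$truth$eles[g2$truth$eles$tissues == "spike", ][1L, ]
  ele_sum <- function(genome, e, seed) {
    ct_k <- simulate_ctss(genome, seed = seed)
    ink <- ct_k$positions$chrom == e$chrom &
      ct_k$positions$pos >= e$start & ct_k$positions$pos < e$end
    sum(ct_k$counts[ink, ct_k$samples$tissue == "spike"])
  }
  tot1 <- sum(vapply(1:60, function(k) ele_sum(g, e, 1000L + k), 0))
  tot2 <- sum(vapply(1:60, function(k) ele_sum(g2, e2, 1000L + k), 0))
  expect_lt(abs(tot2 / tot1 - 2), 0.25)
})

test_that("sample totals sit within 3 Poisson SDs of expectation", {
  g <- generate_genome(small_cfg())
  ct <- simulate_ctss(g)
  truth <- g$truth
  for (s in seq_len(nrow(ct$samples))) {
    tis <- ct$samples$tissue[s]
    mu <- sum(truth$gene_expr[truth$genes$class == "active", tis]) +
      2 * sum(truth$ele_expr[, tis]) +
      2 * 3 * g$config$noise_rate * g$config$chrom_length_bp +
      (if (tis == g$config$tissue_labels[1L] &&
             ct$samples$replicate[s] == 1L)
        4 * sum(truth$genes$class == "weak") else 0)
    expect_lt(abs(sum(ct$counts[, s]) - mu), 3 * sqrt(mu) + 1)
  }
})

test_that("epigenome marks planted features and methylates TE bodies", {
  g <- generate_genome(small_cfg())
  ep <- simulate_epigenome(g)
  eles <- g$truth$eles
  for (i in seq_len(nrow(eles))) {
    ov <- overlap_query(data.frame(chrom = eles$chrom[i],
                                   start = eles$start[i],
                                   end = eles$end[i]),
                        ep$peaks$H3K9ac)
    expect_gte(nrow(ov), 1L)
  }
  # TE without an ELE stays hyper-methylated in CG
  meth <- ep$methylation
  te_free <- g$te_table[!g$te_table$te_id %in% eles$host_te, ][1L, ]
  m <- meth[meth$chrom == te_free$chrom & meth$pos >= te_free$start &
              meth$pos < te_free$end & meth$context == "CG", ]
  ratio <- methylation_ratio(m$methylated_reads, m$total_reads)
  expect_gte(mean(ratio, na.rm = TRUE), 0.8)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(replicates_per_tissue = 1L), ">= 2")
  expect_error(sim_config(noise_rate = 2), "\\[0, 1\\]")
  expect_error(generate_genome(sim_config(n_genes = 500L,
                                          chrom_length_bp = 1e6)),
               "too short")
})

test_that("written dataset files are complete and re-readable", {
  sim <- simulate_dataset(small_cfg())
  d <- tempfile("ds_")
  files <- write_dataset(sim, d)
  expect_true(all(c("genome.fa", "genes.gff3", "ctss.tsv", "te_table.tsv",
                    "hmm_bins.tsv", "methylation.tsv", "homeologs.tsv",
                    "truth_eles.tsv") %in% names(files)))
  ct <- read_ctss(file.path(d, "ctss.tsv"))
  expect_identical(ct$counts, sim$ctss$counts)
  te <- read_te_table(file.path(d, "te_table.tsv"))
  expect_equal(nrow(te), nrow(sim$genome$te_table))
})
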