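# Hierarchical TSS classification: gene windows, the 3-kb intergenic
# rule, ELE mark calling, chromatin-state rescue, and the exhaustive
# partition.

gm1 <- make_gene_models(data.frame(
  gene_id = c("gA", "gB"), chrom = "c1",
  start = c(10000L, 40000L), end = c(13000L, 43000L),
  strand = c("+", "-"), stringsAsFactors = FALSE))

mk_cluster <- function(start, end, strand = "+", dominant = NULL,
                       weak = FALSE) {
  data.frame(chrom = "c1", start = start, end = end, strand = strand,
             dominant_pos = if (is.null(dominant)) start else dominant,
             weak = weak, stringsAsFactors = FALSE)
}

test_that("gene assignment honours the 5'UTR-or-500-bp-upstream rule", {
  # 400 bp upstream of the + strand TSS (10000)
  expect_equal(assign_gene_tss(mk_cluster(9600L, 9610L), gm1), "gA")
  # 600 bp upstream: outside the window
  expect_true(is.na(assign_gene_tss(mk_cluster(9390L, 9400L), gm1)))
  # inside the 5'UTR but far from the TSS start
  expect_equal(assign_gene_tss(mk_cluster(10150L, 10160L), gm1), "gA")
  # minus-strand gene: TSS at 42999, upstream window is to the right
  expect_equal(assign_gene_tss(mk_cluster(43100L, 43110L, "-"), gm1), "gB")
  expect_true(is.na(assign_gene_tss(mk_cluster(43100L, 43110L, "+"), gm1)))
})

test_that("ambiguous assignments go to the nearest TSS then lexical id", {
  gm <- make_gene_models(data.frame(
    gene_id = c("g2", "g1"), chrom = "c1", start = c(1000L, 1400L),
    end = c(4000L, 4400L), strand = "+", stringsAsFactors = FALSE))
  # cluster overlapping g2's 5'UTR and g1's upstream window, dominant
  # position nearer g2's TSS
  expect_equal(assign_gene_tss(mk_cluster(1150L, 1450L, dominant = 1160L),
                               gm), "g2")
  # same cluster but dominant position nearer g1's TSS
  expect_equal(assign_gene_tss(mk_cluster(1150L, 1450L, dominant = 1390L),
                               gm), "g1")
  gm_tie <- make_gene_models(data.frame(
    gene_id = c("gz", "ga"), chrom = "c1", start = c(1000L, 1000L),
    end = c(4000L, 4000L), strand = "+", stringsAsFactors = FALSE))
  expect_equal(assign_gene_tss(mk_cluster(1050L, 1060L), gm_tie), "ga")
})

test_that("the 3-kb intergenic rule is strict at the boundary", {
  # gA spans [10000, 13000); gap of exactly 3000 -> proximal
  expect_false(find_intergenic(mk_cluster(16000L, 16010L), gm1))
  # gap of 3001 -> intergenic
  expect_true(find_intergenic(mk_cluster(16001L, 16010L), gm1))
  # chromosome without genes: everything intergenic
  empty_gm <- list(genes = gm1$genes[0, ], utr5 = gm1$utr5[0, ],
                   exons = gm1$exons[0, ])
  expect_true(find_intergenic(mk_cluster(5L, 10L), empty_gm))
})

test_that("ELE calling requires an active mark overlap", {
  peaks <- list(H3K9ac = data.frame(chrom = "c1", start = 20000L,
                                    end = 20500L),
                H3K4me3 = data.frame(chrom = "c1", start = 30000L,
                                     end = 30500L))
  expect_equal(call_ele_tss(mk_cluster(20100L, 20110L), peaks), "H3K9ac")
  expect_true(is.na(call_ele_tss(mk_cluster(25000L, 25010L), peaks)))
  both <- list(H3K4me3 = peaks$H3K9ac, H3K9ac = peaks$H3K9ac)
  expect_equal(call_ele_tss(mk_cluster(20100L, 20110L), both),
               "H3K4me3,H3K9ac")
})

test_that("state rescue needs the TSS state and a gene context", {
  states <- data.frame(chrom = "c1",
                       start = seq(0L, 49500L, by = 500L),
                       end = seq(500L, 50000L, by = 500L))
  states$state <- 1L
  states$state[states$start == 12000L] <- 5L  # inside gA's body
  states$state[states$start == 25000L] <- 5L  # 12 kb from any gene
  rescued <- rescue_lc_gene_tss(mk_cluster(12010L, 12020L,
                                           dominant = 12010L, weak = TRUE),
                                states, 5L, gm1)
  expect_equal(rescued, "gA")
  # TSS-state bin far from genes: not rescued
  expect_true(is.na(rescue_lc_gene_tss(mk_cluster(25010L, 25020L,
                                                  dominant = 25010L,
                                                  weak = TRUE),
                                       states, 5L, gm1)))
  # non-TSS-state bin: not rescued
  expect_true(is.na(rescue_lc_gene_tss(mk_cluster(11010L, 11020L,
                                                  dominant = 11010L,
                                                  weak = TRUE),
                                       states, 5L, gm1)))
})

test_that("annotation is an exhaustive, order-invariant partition", {
  clusters <- rbind(mk_cluster(9600L, 9610L),             # gene_tss
                    mk_cluster(20100L, 20110L),           # ele_tss
                    mk_cluster(25000L, 25010L),           # intergenic_other
                    mk_cluster(15000L, 15010L),           # proximal
                    mk_cluster(12010L, 12020L, weak = TRUE))  # lc rescue
  peaks <- list(H3K9ac = data.frame(chrom = "c1", start = 20000L,
                                    end = 20500L))
  states <- data.frame(chrom = "c1", start = 12000L, end = 12500L,
                       state = 5L)
  ann <- annotate_clusters(clusters, gm1, peaks, states, 5L)
  expect_equal(as.vector(ann$counts),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(ann$counts), nrow(clusters))
  expect_equal(as.character(ann$annotation$category),
               c("gene_tss", "ele_tss", "intergenic_other",
                 "proximal_unclassified", "lc_gene_tss"))
  # shuffling input order changes no category
  for (perm in list(c(5, 3, 1, 4, 2), c(2, 4, 5, 1, 3))) {
    ann2 <- annotate_clusters(clusters[perm, ], gm1, peaks, states, 5L)
    expect_equal(as.character(ann2$annotation$category),
                 as.character(ann$annotation$category)[perm])
  }
  # empty peaks: no ELEs
  ann0 <- annotate_clusters(clusters, gm1,
                            list(H3K9ac = peaks$H3K9ac[0, ]), states, 5L)
  expect_equal(unname(ann0$counts["ele_tss"]), 0L)
  # weak clusters are never ELEs even on a marked intergenic locus
  wk <- mk_cluster(20100L, 20110L, weak = TRUE)
  annw <- annotate_clusters(wk, gm1, peaks, states, 5L)
  expect_equal(as.character(annw$annotation$category), "intergenic_other")
})

test_that("planted ELEs and sharp gene TSSs are annotated correctly", {
  run <- shared_run()
  truth <- run$sim$genome$truth
  ev <- evaluate_ele_calls(run$eles, truth$eles)
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$precision, 0.9)
  # sharp active gene TSS assignment accuracy
  ann <- run$annotation$annotation
  sharp <- truth$genes[truth$genes$class == "active" &
                         truth$genes$shape == "sharp", ]
  ok <- vapply(seq_len(nrow(sharp)), function(i) {
    any(!is.na(ann$assigned_gene) &
          ann$assigned_gene == sharp$gene_id[i] &
          ann$category == "gene_tss")
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
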