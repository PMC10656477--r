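# TE assignment, Fisher enrichment, LTR dating, PWM scanning and
# metaprofiles.

test_that("TE assignment is by dominant-position containment, innermost wins", {
  te <- data.frame(te_id = c("outer", "inner", "other"), chrom = "c1",
                   start = c(1000L, 1200L, 9000L),
                   end = c(4000L, 1600L, 9500L), strand = "+",
                   superfamily = "RLG", family = "RLG_famc7",
                   subfamily = c("RLG_famc7.1", "RLG_famc7.3",
                                 "RLG_famc7.1"),
                   full_length = FALSE, stringsAsFactors = FALSE)
  eles <- data.frame(ele_id = c("a", "b", "c"), chrom = "c1",
                     start = c(1300L, 3990L, 5000L),
                     end = c(1310L, 4100L, 5010L),
                     dominant_pos = c(1300L, 4050L, 5000L))
  out <- assign_te(eles, te)
  expect_equal(out$te_id, c("inner", NA, NA))
  expect_equal(out$subfamily[1L], "RLG_famc7.3")
})

test_that("two-tailed Fisher p matches exhaustive enumeration", {
  got <- fisher_exact_2x2(3L, 1L, 1L, 3L)
  expect_equal(got$p, 0.485714285714286, tolerance = 1e-10)
  expect_equal(got$odds_ratio, 9)
  sym1 <- fisher_exact_2x2(0L, 5L, 5L, 0L)
  sym2 <- fisher_exact_2x2(5L, 0L, 0L, 5L)
  expect_equal(sym1$p, sym2$p)
  degenerate <- fisher_exact_2x2(0L, 0L, 0L, 0L)
  expect_equal(degenerate$p, 1)
  expect_true(is.na(degenerate$odds_ratio))

  set.seed(91)
  for (rep in 1:200) {
    cells <- as.integer(sample(0:15, 4L, replace = TRUE))
    if (sum(cells) == 0L) next
    got <- fisher_exact_2x2(cells[1L], cells[2L], cells[3L], cells[4L])
    want <- oracle_fisher(cells[1L], cells[2L], cells[3L], cells[4L])
    expect_equal(got$p, want, tolerance = 1e-12)
  }
})

test_that("family enrichment flags a constructed over-represented group", {
  te <- data.frame(te_id = sprintf("t%03d", 1:160), chrom = "c1",
                   start = (1:160) * 1000L, end = (1:160) * 1000L + 500L,
                   strand = "+", superfamily = "RLG",
                   family = rep(c("RLG_famc7", "RLG_famc9"), c(60, 100)),
                   subfamily = rep(c("RLG_famc7.3", "RLG_famc9.1"),
                                   c(60, 100)),
                   full_length = FALSE, stringsAsFactors = FALSE)
  bearing <- c(sprintf("t%03d", 1:50),     # 50/60 of famc7.3
               sprintf("t%03d", 61:65))    # 5/100 of famc9.1
  assign <- data.frame(ele_id = seq_along(bearing), te_id = bearing,
                       subfamily = te$subfamily[match(bearing, te$te_id)],
                       family = te$family[match(bearing, te$te_id)])
  res <- family_enrichment(assign, te, level = "subfamily")
  expect_equal(res$group[1L], "RLG_famc7.3")
  expect_gt(res$odds_ratio[1L], 1)
  expect_lt(res$q[1L], 0.05)
  near_null <- res[res$group == "RLG_famc9.1", ]
  expect_lt(near_null$odds_ratio, 1)
})

test_that("LTR alignment matches the brute-force scoring oracle", {
  a <- align_ltr_pair("ACGT", "AGT")
  expect_equal(nchar(a$aligned5), nchar(a$aligned3))
  gaps <- sum(strsplit(a$aligned3, "")[[1L]] == "-") +
    sum(strsplit(a$aligned5, "")[[1L]] == "-")
  expect_equal(gaps, 1L)
  expect_equal(a$score, oracle_global_align("ACGT", "AGT"))

  s <- random_dna(80)
  ident <- align_ltr_pair(s, s)
  expect_identical(ident$aligned5, ident$aligned3)
  expect_equal(ident$score, 80)

  set.seed(101)
  for (rep in 1:40) {
    s1 <- random_dna(sample(1:8, 1L))
    s2 <- random_dna(sample(1:8, 1L))
    expect_equal(align_ltr_pair(s1, s2)$score,
                 oracle_global_align(s1, s2),
                 info = paste(s1, s2))
  }
  expect_error(align_ltr_pair("", "ACGT"), "non-empty")
})

test_that("K2P distance matches closed form and saturates correctly", {
  ident <- kimura_2p(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(ident$P, 0)
  expect_equal(ident$Q, 0)
  expect_equal(ident$d, 0)

  # 100 sites with 10 transitions and 5 transversions: P=0.1, Q=0.05
  x <- strrep("A", 100)
  y <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  k <- kimura_2p(x, y)
  expect_equal(k$P, 0.1)
  expect_equal(k$Q, 0.05)
  expect_equal(k$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_equal(k$d, 0.17018, tolerance = 1e-4)

  sat <- kimura_2p(strrep("A", 10), strrep("G", 5) |>
                     paste0(strrep("C", 5)))
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))

  # gap/N columns excluded from the site count
  g <- kimura_2p("AC-GT", "ACNGT")
  expect_equal(g$sites, 4L)
  g2 <- kimura_2p("AC-GN", "ACNGT")
  expect_equal(g2$sites, 3L)

  # d >= p-distance wherever defined; first-order agreement at low d
  set.seed(111)
  for (rep in 1:30) {
    P <- runif(1, 0, 0.01); Q <- runif(1, 0, 0.01)
    n <- 1000L
    nP <- round(P * n); nQ <- round(Q * n)
    y <- paste0(strrep("G", nP), strrep("C", nQ), strrep("A", n - nP - nQ))
    k <- kimura_2p(strrep("A", n), y)
    expect_gte(k$d, k$P + k$Q - 1e-12)
    if (k$P + k$Q > 0)
      expect_lt(abs(k$d - (k$P + k$Q)) / (k$P + k$Q), 0.05)
  }
})

test_that("insertion time applies the percent-distance formula", {
  expect_equal(insertion_time(2.6, 1.3e-8), 1e6)
  expect_equal(insertion_time(0), 0)
  expect_equal(insertion_time(1, 0.65e-8), 2 * insertion_time(1, 1.3e-8))
  expect_error(insertion_time(-1), "non-negative")
})

test_that("simulated LTR pairs of known age are dated within 10%", {
  mu <- 1.3e-8
  age <- 1e6                      # generations
  d_true <- 2 * mu * age          # pairwise divergence
  pairs <- do.call(rbind, lapply(1:200, function(i) {
    pr <- simulate_ltr_pair(300L, d_true, seed = 7000L + i)
    data.frame(te_id = paste0("L", i), ltr5 = pr$ltr5, ltr3 = pr$ltr3,
               stringsAsFactors = FALSE)
  }))
  ages <- ltr_age(pairs, mu = mu)
  expect_true(all(!ages$saturated))
  expect_lt(abs(mean(ages$time_generations) - age) / age, 0.10)
})

test_that("PWM scanning counts consensus hits on both strands", {
  consensus <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "T")))
  consensus[cbind(1:4, 1:4)] <- 1
  counts <- scan_pwm(c(s1 = "ACGTACGT"), list(m = consensus))
  expect_equal(unname(counts["s1", "m"]), 4L)  # ACGT is its own complement
  fwd_only <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "T")))
  fwd_only[cbind(c(1, 1, 2, 3), 1:4)] <- 1     # AACG
  c1 <- scan_pwm(c(s = "TTAACGTT"), list(m = fwd_only))
  c2 <- scan_pwm(c(s = "AACGTTAA"), list(m = fwd_only))
  expect_equal(unname(c1["s", "m"]), unname(c2["s", "m"]))
  # uniform PWM can never reach the maximal-score fallback informatively
  unif <- matrix(0.25, 4L, 6L, dimnames = list(c("A", "C", "G", "T")))
  expect_equal(sum(scan_pwm(c(s = random_dna(100)), list(u = unif),
                            p_max = 1e-4)), 0L)
  bad <- consensus; bad[1L, 1L] <- 0.5
  expect_error(scan_pwm(c(s = "ACGT"), list(m = bad)), "sum to 1")
})

test_that("PWM hit sets equal brute-force sliding-window rescoring", {
  set.seed(121)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    w <- sample(4:8, 1L)
    pwm <- matrix(rexp(4 * w), 4L, dimnames = list(bases))
    pwm <- sweep(pwm, 2L, colSums(pwm), "/")
    lo <- log2(pmax(pwm, 1e-9) / 0.25)
    thr <- eletools:::.pwm_threshold(lo, rep(0.25, 4L), 1e-2)
    seqs <- vapply(1:5, function(i) random_dna(200L), "")
    names(seqs) <- paste0("s", 1:5)
    got <- scan_pwm(seqs, list(m = pwm), p_max = 1e-2)
    for (s in names(seqs)) {
      want <- oracle_pwm_hits(seqs[[s]], lo, thr) +
        oracle_pwm_hits(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seqs[[s]]))), lo, thr)
      expect_equal(unname(got[s, "m"]), want)
    }
  }
})

test_that("motif abundance comparison handles identical and separated groups", {
  a <- matrix(c(2L, 2L, 2L), 3L, dimnames = list(NULL, "m"))
  b <- matrix(c(0L, 0L, 0L), 3L, dimnames = list(NULL, "m"))
  res <- compare_motif_abundance(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  sep <- compare_motif_abundance(a, b)
  expect_equal(sep$abundance_a, 2)
  expect_equal(sep$abundance_b, 0)
  expect_equal(sep$p, 0)
  expect_true(is.infinite(sep$t))
  tiny <- compare_motif_abundance(a[1, , drop = FALSE], b)
  expect_true(is.na(tiny$p))
})

test_that("metaprofiles orient by strand and pad chromosome edges", {
  track <- data.frame(chrom = "c1", pos = 0:9999,
                      value = rep(1, 10000))
  anchors <- data.frame(chrom = "c1", pos = 5000L, strand = "+")
  mp <- metaprofile(track, anchors, flank = 1000L, bin = 100L)
  expect_equal(unname(mp$profile), rep(1, 20))
  # impulse lands in the central bin and mirrors on the minus strand
  imp <- data.frame(chrom = "c1", pos = 5333L, value = 10)
  plus <- metaprofile(imp, anchors, flank = 1000L, bin = 100L)
  expect_equal(unname(which(plus$matrix[1L, ] > 0)), 14L)
  minus <- metaprofile(imp, data.frame(chrom = "c1", pos = 5000L,
                                       strand = "-"),
                       flank = 1000L, bin = 100L)
  expect_equal(unname(which(minus$matrix[1L, ] > 0)), 7L)
  # anchor near the chromosome start: upstream bins missing
  edge <- metaprofile(track, data.frame(chrom = "c1", pos = 200L,
                                        strand = "+"),
                      flank = 1000L, bin = 100L)
  expect_true(all(is.na(edge$matrix[1L, 1:10])))
})

test_that("planted synthetic data ranks the expanded subfamily first", {
  run <- shared_run()
  expect_equal(run$family_enr$group[1L], "RLG_famc7.3")
  te <- run$tissue_enr
  expect_equal(unname(unlist(te[which.min(te$q), c("group", "tissue")])),
               c("RLG_famc7.3", "spike"))
})
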