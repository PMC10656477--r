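# Independent oracles used across the suite: brute-force implementations
# kept deliberately separate from the package's own code paths.

# O(n^2) transitive-closure clustering of thresholded positions.
oracle_cluster <- function(pos, value, max_dist, threshold) {
  p <- pos[value >= threshold]
  if (length(p) == 0L)
    return(data.frame(start = integer(), end = integer()))
  n <- length(p)
  adj <- abs(outer(p, p, "-")) <= max_dist
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- t(vapply(unique(comp), function(cc)
    c(min(p[comp == cc]), max(p[comp == cc]) + 1L), integer(2)))
  out <- out[order(out[, 1L]), , drop = FALSE]
  data.frame(start = as.integer(out[, 1L]), end = as.integer(out[, 2L]))
}

# Independent affine-gap Gotoh DP (gap of length L costs open + L * ext).
oracle_global_align <- function(s1, s2, match = 1, mismatch = -2,
                                open = 5, ext = 1) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- E <- F <- matrix(NEG, n + 1L, m + 1L)
  H[1L, 1L] <- 0
  for (j in seq_len(m) + 1L) {
    E[1L, j] <- max(E[1L, j - 1L] - ext, H[1L, j - 1L] - open - ext)
    H[1L, j] <- E[1L, j]
  }
  for (i in seq_len(n) + 1L) {
    F[i, 1L] <- max(F[i - 1L, 1L] - ext, H[i - 1L, 1L] - open - ext)
    H[i, 1L] <- F[i, 1L]
    for (j in seq_len(m) + 1L) {
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      E[i, j] <- max(E[i, j - 1L] - ext, H[i, j - 1L] - open - ext)
      F[i, j] <- max(F[i - 1L, j] - ext, H[i - 1L, j] - open - ext)
      H[i, j] <- max(H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
    }
  }
  H[n + 1L, m + 1L]
}

oracle_local_align <- function(s1, s2, match = 1, mismatch = -2,
                               open = 5, ext = 1) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- F <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      E[i, j] <- max(E[i, j - 1L] - ext, H[i, j - 1L] - open - ext)
      F[i, j] <- max(F[i - 1L, j] - ext, H[i - 1L, j] - open - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive two-tailed Fisher p by hypergeometric enumeration.
oracle_fisher <- function(a, b, c_, d_) {
  r1 <- a + b; r2 <- c_ + d_; c1 <- a + c_
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# HMM log-likelihood by exhaustive path enumeration (Bernoulli emissions).
oracle_hmm_loglik <- function(pi, Tm, E, M) {
  n <- nrow(M); S <- length(pi)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  tot <- 0
  for (k in seq_len(nrow(paths))) {
    st <- paths[k, ]
    p <- pi[st[1L]]
    if (n > 1L) for (t in 2:n) p <- p * Tm[st[t - 1L], st[t]]
    for (t in seq_len(n)) {
      e <- E[st[t], ]
      p <- p * prod(ifelse(M[t, ] == 1, e, 1 - e))
    }
    tot <- tot + p
  }
  log(tot)
}

# Sample an observation chain from a Bernoulli-emission HMM.
sample_hmm_chain <- function(pi, Tm, E, n, seed) {
  set.seed(seed)
  S <- length(pi)
  states <- integer(n)
  states[1L] <- sample.int(S, 1L, prob = pi)
  for (t in 2:n)
    states[t] <- sample.int(S, 1L, prob = Tm[states[t - 1L], ])
  M <- matrix(0L, n, ncol(E))
  for (t in seq_len(n))
    M[t, ] <- rbinom(ncol(E), 1L, E[states[t], ])
  colnames(M) <- colnames(E)
  list(states = states, M = M)
}

# Match estimated states to generating states by emission distance.
match_states <- function(E_est, E_true) {
  S <- nrow(E_true)
  perms <- as.matrix(expand.grid(rep(list(seq_len(S)), S)))
  perms <- perms[apply(perms, 1L, function(x) length(unique(x)) == S), ,
                 drop = FALSE]
  costs <- apply(perms, 1L, function(pm)
    sum(abs(E_est[pm, , drop = FALSE] - E_true)))
  perms[which.min(costs), ]
}

# Direct sliding-window PWM rescoring.
oracle_pwm_hits <- function(seq, lo, thr) {
  chars <- strsplit(seq, "")[[1L]]
  idx <- match(chars, c("A", "C", "G", "T"))
  w <- ncol(lo); L <- length(idx)
  if (L < w || !is.finite(thr)) return(0L)
  hits <- 0L
  for (i in seq_len(L - w + 1L)) {
    sc <- sum(lo[cbind(idx[i:(i + w - 1L)], seq_len(w))])
    if (!is.na(sc) && round(sc * 1000) / 1000 >= thr - 1e-9) hits <- hits + 1L
  }
  hits
}

# Small gene-model fixture: one gene per row of `df` (gene_id, chrom,
# start, end, strand) with a 200-bp 5'UTR at the 5' end and one exon
# spanning the gene.
make_gene_models <- function(df) {
  utr <- df
  utr$start <- ifelse(df$strand == "-", df$end - 200L, df$start)
  utr$end <- ifelse(df$strand == "-", df$end, df$start + 200L)
  list(
    genes = data.frame(gene_id = df$gene_id, chrom = df$chrom,
                       start = df$start, end = df$end, strand = df$strand,
                       tss = ifelse(df$strand == "-", df$end - 1L, df$start),
                       stringsAsFactors = FALSE),
    utr5 = data.frame(gene_id = df$gene_id, chrom = utr$chrom,
                      start = utr$start, end = utr$end, strand = df$strand,
                      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = df$gene_id, chrom = df$chrom,
                       start = df$start, end = df$end, strand = df$strand,
                       stringsAsFactors = FALSE))
}

# One shared default pipeline run, computed once per session.
.shared_env <- new.env(parent = emptyenv())
shared_run <- function() {
  if (is.null(.shared_env$run)) {
    .shared_env$run <- run_all(run_config(outdir = tempfile("shared_run_"),
                                          seed = 1L, verbose = FALSE))
  }
  .shared_env$run
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
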