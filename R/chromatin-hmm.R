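# Multivariate Bernoulli-emission hidden Markov model over binarized
# fixed-width genomic bins. Used to segment the genome into chromatin
# states from combinatorial epigenomic/transcriptomic signals and to
# identify the TSS-active state (CAGE + H3K4me3 + H3K9ac) that rescues
# low-confidence gene TSSs.

#' Binarize a per-bin count matrix
#'
#' Default rule: a bin is marked 1 for a track iff the upper-tail
#' probability of its count under a Poisson with the track-wide mean is
#' below `p_cutoff` (the convention of binarized chromatin segmentation).
#'
#' @param counts non-negative matrix, bins x tracks, with track column
#'   names; bins must tile each chromosome contiguously (rows grouped per
#'   chromosome via the `chrom` attribute or a `chrom` argument).
#' @param p_cutoff Poisson upper-tail probability threshold. Default 1e-4.
#' @return binary integer matrix of the same shape.
#' @export
binarize_tracks <- function(counts, p_cutoff = 1e-4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  out <- matrix(0L, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    lambda <- mean(counts[, j])
    if (lambda == 0) {
      warning(sprintf("track '%s' is all zero; emitted all-zero",
                      colnames(counts)[j]))
      next
    }
    # P(X >= x | lambda) < p_cutoff
    tail_p <- ppois(counts[, j] - 1, lambda, lower.tail = FALSE)
    out[, j] <- as.integer(tail_p < p_cutoff)
  }
  out
}

# Log emission probabilities: bins x states matrix of log P(obs_i | state).
# E may contain exact 0/1; -Inf rows are legitimate (impossible emissions).
.log_emission <- function(M, E) {
  logE <- log(E)
  log1E <- log(1 - E)
  # avoid 0 * -Inf = NaN in the matrix products, then restore exact -Inf
  # for genuinely impossible (bin, state) emissions
  logE_f <- ifelse(is.finite(logE), logE, 0)
  log1E_f <- ifelse(is.finite(log1E), log1E, 0)
  logb <- M %*% t(logE_f) + (1 - M) %*% t(log1E_f)
  impossible <- (M %*% t(E == 0) + (1 - M) %*% t(E == 1)) > 0
  logb[impossible] <- -Inf
  logb
}

# Scaled forward pass. Returns list(loglik, alpha, scale) or loglik = -Inf
# when an observation has zero probability under the model.
.forward <- function(logb, pi, Tm) {
  n <- nrow(logb); S <- ncol(logb)
  b <- exp(logb)
  alpha <- matrix(0, n, S)
  scale <- numeric(n)
  a <- pi * b[1L, ]
  scale[1L] <- sum(a)
  if (scale[1L] == 0) return(list(loglik = -Inf))
  alpha[1L, ] <- a / scale[1L]
  for (t in seq_len(n)[-1L]) {
    a <- (alpha[t - 1L, ] %*% Tm) * b[t, ]
    scale[t] <- sum(a)
    if (scale[t] == 0) return(list(loglik = -Inf))
    alpha[t, ] <- a / scale[t]
  }
  list(loglik = sum(log(scale)), alpha = alpha, scale = scale)
}

.backward <- function(logb, Tm, scale) {
  n <- nrow(logb); S <- ncol(logb)
  b <- exp(logb)
  beta <- matrix(0, n, S)
  beta[n, ] <- 1
  for (t in rev(seq_len(n - 1L))) {
    beta[t, ] <- (Tm %*% (b[t + 1L, ] * beta[t + 1L, ])) / scale[t + 1L]
  }
  beta
}

.as_chain_list <- function(tracks) {
  if (is.matrix(tracks)) return(list(tracks))
  if (is.list(tracks) && !is.data.frame(tracks)) return(tracks)
  .stopf("tracks must be a binary matrix or a list of per-chromosome matrices")
}

#' Log-likelihood of binned tracks under a chromatin HMM
#'
#' Scaled forward algorithm; returns `-Inf` when the data are impossible
#' under the model.
#'
#' @param model `chromatin_hmm` object.
#' @param tracks binary bins x tracks matrix, or a list of such matrices
#'   (one chain per chromosome).
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(model, tracks) {
  chains <- .as_chain_list(tracks)
  .check_tracks(model, chains)
  ll <- 0
  for (M in chains) {
    logb <- .log_emission(M, model$emissions)
    f <- .forward(logb, model$initial, model$transitions)
    if (!is.finite(f$loglik)) return(-Inf)
    ll <- ll + f$loglik
  }
  ll
}

.check_tracks <- function(model, chains) {
  for (M in chains) {
    if (is.null(colnames(M)) || is.null(colnames(model$emissions)) ||
        !identical(colnames(M), colnames(model$emissions)))
      .stopf("track names of data and model do not match")
  }
}

#' Fit a Bernoulli-emission chromatin HMM by Baum-Welch
#'
#' Expectation-maximization with scaled forward-backward recursions;
#' emissions are independent Bernoulli per track. The per-iteration
#' log-likelihood is checked to be non-decreasing (within 1e-8). Several
#' random restarts are run from seed-derived sub-seeds and the best final
#' log-likelihood wins (ties by restart index).
#'
#' @param tracks binary bins x tracks matrix (column names required), or a
#'   list of such matrices, one per chromosome.
#' @param n_states number of hidden states (>= 2). Default 15.
#' @param seed integer seed controlling all restarts.
#' @param n_restarts random restarts. Default 5.
#' @param max_iter maximum EM iterations per restart. Default 200.
#' @param tol stop when the log-likelihood improves by less than this.
#' @return object of class `chromatin_hmm`: `n_states`, `tracks`,
#'   `initial`, `transitions`, `emissions`, `loglik`, `n_iter`,
#'   `converged`.
#' @export
hmm_fit <- function(tracks, n_states = 15L, seed = 1L, n_restarts = 5L,
                    max_iter = 200L, tol = 1e-6) {
  if (n_states < 2L) .stopf("n_states must be >= 2")
  chains <- .as_chain_list(tracks)
  track_names <- colnames(chains[[1L]])
  if (is.null(track_names)) .stopf("tracks must have column names")
  n_bins <- sum(vapply(chains, nrow, 0L))
  if (n_bins < 10L * n_states)
    .stopf("need at least 10 bins per state (%d bins for %d states)",
           n_bins, n_states)
  if (all(vapply(chains, function(M) nrow(unique(M)) == 1L, TRUE)))
    warning("all bins identical; fit is degenerate")
  Tn <- length(track_names)
  seeds <- .sub_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .with_seed(seeds[r], list(
      pi = {
        x <- runif(n_states, 0.5, 1.5); x / sum(x)
      },
      Tm = {
        Tm <- matrix(runif(n_states^2, 0, 0.2), n_states)
        diag(Tm) <- diag(Tm) + 1
        Tm / rowSums(Tm)
      },
      E = matrix(runif(n_states * Tn, 0.05, 0.95), n_states, Tn,
                 dimnames = list(NULL, track_names))
    ))
    fit <- .baum_welch(chains, init$pi, init$Tm, init$E, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart <- r
    }
  }
  best$n_states <- as.integer(n_states)
  best$tracks <- track_names
  class(best) <- "chromatin_hmm"
  best
}

.baum_welch <- function(chains, pi, Tm, E, max_iter, tol) {
  eps <- 1e-6
  S <- length(pi)
  prev_ll <- -Inf
  converged <- FALSE
  iter <- 0L
  ll_trace <- numeric()
  for (iter in seq_len(max_iter)) {
    ll <- 0
    pi_acc <- numeric(S)
    T_num <- matrix(0, S, S)
    E_num <- matrix(0, S, ncol(E))
    gamma_sum <- numeric(S)
    for (M in chains) {
      logb <- .log_emission(M, E)
      f <- .forward(logb, pi, Tm)
      if (!is.finite(f$loglik)) .stopf("zero-probability data during EM")
      beta <- .backward(logb, Tm, f$scale)
      gamma <- f$alpha * beta
      gamma <- gamma / rowSums(gamma)
      ll <- ll + f$loglik
      n <- nrow(M)
      b <- exp(logb)
      if (n > 1L) {
        # sum over t of xi_t = Tm (*) outer(alpha_t, b_{t+1} beta_{t+1}/c_{t+1})
        right <- b[-1L, , drop = FALSE] * beta[-1L, , drop = FALSE] /
          f$scale[-1L]
        T_num <- T_num +
          Tm * crossprod(f$alpha[-n, , drop = FALSE], right)
      }
      pi_acc <- pi_acc + gamma[1L, ]
      E_num <- E_num + t(gamma) %*% M
      gamma_sum <- gamma_sum + colSums(gamma)
    }
    if (ll < prev_ll - 1e-8)
      warning(sprintf("EM log-likelihood decreased at iteration %d", iter))
    ll_trace <- c(ll_trace, ll)
    improved <- ll - prev_ll
    prev_ll <- ll
    # M-step
    pi <- pi_acc / sum(pi_acc)
    Tm <- T_num / rowSums(T_num)
    E <- E_num / gamma_sum
    E[E < eps] <- eps
    E[E > 1 - eps] <- 1 - eps
    if (is.finite(improved) && improved >= 0 && improved < tol) {
      converged <- TRUE
      break
    }
  }
  colnames(E) <- colnames(chains[[1L]])
  list(initial = pi, transitions = Tm, emissions = E,
       loglik = prev_ll, ll_trace = ll_trace, n_iter = iter,
       converged = converged)
}

#' @export
print.chromatin_hmm <- function(x, ...) {
  cat(sprintf("chromatin_hmm: %d states over tracks [%s]\n", x$n_states,
              paste(x$tracks, collapse = ", ")))
  cat(sprintf("  log-likelihood %.3f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "iteration cap"))
  invisible(x)
}

#' @export
logLik.chromatin_hmm <- function(object, ...) {
  S <- object$n_states; Tn <- length(object$tracks)
  val <- object$loglik
  attr(val, "df") <- (S - 1) + S * (S - 1) + S * Tn
  class(val) <- "logLik"
  val
}

#' Decode per-bin chromatin states
#'
#' Posterior (forward-backward) argmax per bin; ties broken toward the
#' lower state index. Viterbi decoding is available with
#' `method = "viterbi"`.
#'
#' @param model `chromatin_hmm`.
#' @param tracks binary matrix or list of per-chromosome matrices.
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @return integer state labels (1-based); a list when `tracks` is a list.
#' @export
hmm_decode <- function(model, tracks, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  chains <- .as_chain_list(tracks)
  .check_tracks(model, chains)
  out <- lapply(chains, function(M) {
    logb <- .log_emission(M, model$emissions)
    if (method == "posterior") {
      f <- .forward(logb, model$initial, model$transitions)
      if (!is.finite(f$loglik)) .stopf("data impossible under model")
      beta <- .backward(logb, model$transitions, f$scale)
      gamma <- f$alpha * beta
      max.col(gamma, ties.method = "first")
    } else {
      .viterbi(logb, model$initial, model$transitions)
    }
  })
  if (is.matrix(tracks)) out[[1L]] else out
}

.viterbi <- function(logb, pi, Tm) {
  n <- nrow(logb); S <- ncol(logb)
  logT <- log(Tm)
  delta <- log(pi) + logb[1L, ]
  psi <- matrix(0L, n, S)
  for (t in seq_len(n)[-1L]) {
    cand <- delta + logT  # S x S: prev state rows
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[t, ], seq_len(S))] + logb[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in rev(seq_len(n - 1L))) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Identify the TSS-active chromatin state
#'
#' The TSS-active (promoter-like) chromatin state is the state
#' maximizing the product of emission probabilities of the CAGE, H3K4me3
#' and H3K9ac tracks; ties break toward the lower state index. State
#' indices are arbitrary across fits, so the state is always identified
#' functionally, never by its number.
#'
#' @param model `chromatin_hmm` whose tracks include `CAGE`, `H3K4me3`,
#'   `H3K9ac`.
#' @return integer state index (1-based).
#' @export
tss_active_state <- function(model) {
  need <- c("CAGE", "H3K4me3", "H3K9ac")
  miss <- setdiff(need, model$tracks)
  if (length(miss) > 0L)
    .stopf("model lacks required track(s): %s", paste(miss, collapse = ", "))
  score <- apply(model$emissions[, need, drop = FALSE], 1L, prod)
  which.max(score)  # which.max returns the first (lowest) index on ties
}
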