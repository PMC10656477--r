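# Bernoulli-emission HMM: binarization, likelihood, EM, decoding and the
# functional identification of the TSS-active state.

test_that("Poisson-tail binarization marks only extreme bins", {
  counts <- matrix(c(0, 10, 1, 1, 1, 1), ncol = 2L,
                   dimnames = list(NULL, c("CAGE", "flat")))
  # column means: CAGE ~ 3.67, flat = 1
  b <- binarize_tracks(counts)
  expect_equal(b[, "flat"], c(0L, 0L, 0L))
  # P(X >= 10 | lambda = 1) ~ 1.1e-7 < 1e-4
  one <- binarize_tracks(matrix(c(rep(1, 99), 10), ncol = 1L,
                                dimnames = list(NULL, "t")))
  expect_equal(sum(one), 1L)
  expect_equal(which(one == 1L), 100L)
  expect_warning(binarize_tracks(matrix(0, 5L, 1L,
                                        dimnames = list(NULL, "z"))),
                 "all zero")
})

test_that("log-likelihood matches exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    S <- sample(2:3, 1L)
    n <- sample(2:8, 1L)
    Tn <- sample(1:3, 1L)
    pi <- runif(S); pi <- pi / sum(pi)
    Tm <- matrix(runif(S * S), S); Tm <- Tm / rowSums(Tm)
    E <- matrix(runif(S * Tn), S, Tn,
                dimnames = list(NULL, paste0("tr", seq_len(Tn))))
    M <- matrix(rbinom(n * Tn, 1L, 0.5), n, Tn,
                dimnames = list(NULL, colnames(E)))
    model <- structure(list(n_states = S, tracks = colnames(E),
                            initial = pi, transitions = Tm, emissions = E),
                       class = "chromatin_hmm")
    expect_equal(hmm_loglik(model, M), oracle_hmm_loglik(pi, Tm, E, M),
                 tolerance = 1e-8)
  }
})

test_that("deterministic emissions give exact and impossible likelihoods", {
  model <- structure(list(n_states = 2L, tracks = "t", initial = c(1, 0),
                          transitions = diag(2),
                          emissions = matrix(c(1, 0), 2L,
                                             dimnames = list(NULL, "t"))),
                     class = "chromatin_hmm")
  M1 <- matrix(1L, 1L, 1L, dimnames = list(NULL, "t"))
  expect_equal(hmm_loglik(model, M1), 0)
  M0 <- matrix(0L, 1L, 1L, dimnames = list(NULL, "t"))
  expect_equal(hmm_loglik(model, M0), -Inf)
  expect_error(hmm_loglik(model, `colnames<-`(M1, "other")), "track names")
})

test_that("Baum-Welch recovers a planted 2-state model and is monotone", {
  E_true <- matrix(c(0.9, 0.1), 2L, dimnames = list(NULL, "t"))
  T_true <- matrix(c(0.95, 0.05, 0.1, 0.9), 2L, byrow = TRUE)
  chain <- sample_hmm_chain(c(0.5, 0.5), T_true, E_true, 10000L, seed = 41L)
  fit <- hmm_fit(chain$M, n_states = 2L, seed = 2L, n_restarts = 3L,
                 max_iter = 300L, tol = 1e-7)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  pm <- match_states(fit$emissions, E_true)
  expect_lt(max(abs(fit$emissions[pm, ] - E_true)), 0.05)
  expect_lt(max(abs(fit$transitions[pm, pm] - T_true)), 0.05)
  # stochasticity preserved
  expect_equal(rowSums(fit$transitions), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(fit$initial), 1, tolerance = 1e-9)

  # decoding accuracy after state matching
  dec <- hmm_decode(fit, chain$M)
  relab <- order(pm)[dec]
  expect_gte(mean(relab == chain$states), 0.95)

  # determinism
  fit2 <- hmm_fit(chain$M, n_states = 2L, seed = 2L, n_restarts = 3L,
                  max_iter = 300L, tol = 1e-7)
  expect_identical(fit$emissions, fit2$emissions)

  expect_error(hmm_fit(chain$M, n_states = 1L), ">= 2")
})

test_that("posterior decoding breaks ties toward the lower state index", {
  model <- structure(list(n_states = 2L, tracks = "t",
                          initial = c(0.5, 0.5),
                          transitions = matrix(0.5, 2L, 2L),
                          emissions = matrix(c(0.5, 0.5), 2L,
                                             dimnames = list(NULL, "t"))),
                     class = "chromatin_hmm")
  M <- matrix(c(1L, 0L, 1L), 3L, dimnames = list(NULL, "t"))
  expect_equal(hmm_decode(model, M), c(1L, 1L, 1L))
  # deterministic emissions: decoded path equals generating path
  det <- structure(list(n_states = 2L, tracks = "t", initial = c(0.5, 0.5),
                        transitions = matrix(0.5, 2L, 2L),
                        emissions = matrix(c(0.99, 0.01), 2L,
                                           dimnames = list(NULL, "t"))),
                   class = "chromatin_hmm")
  M <- matrix(c(1L, 0L, 0L, 1L), 4L, dimnames = list(NULL, "t"))
  expect_equal(hmm_decode(det, M), c(1L, 2L, 2L, 1L))
  expect_equal(hmm_decode(det, M, method = "viterbi"), c(1L, 2L, 2L, 1L))
})

test_that("forward-backward posteriors sum to one per bin", {
  set.seed(51)
  S <- 3L; Tn <- 2L; n <- 50L
  pi <- rep(1 / S, S)
  Tm <- matrix(runif(S * S), S); Tm <- Tm / rowSums(Tm)
  E <- matrix(runif(S * Tn), S, Tn, dimnames = list(NULL, c("a", "b")))
  M <- matrix(rbinom(n * Tn, 1L, 0.5), n, Tn,
              dimnames = list(NULL, colnames(E)))
  logb <- eletools:::.log_emission(M, E)
  f <- eletools:::.forward(logb, pi, Tm)
  beta <- eletools:::.backward(logb, Tm, f$scale)
  gamma <- f$alpha * beta
  expect_equal(rowSums(gamma), rep(1, n), tolerance = 1e-9)
})

test_that("the TSS-active state is identified functionally", {
  E <- matrix(0.1, 3L, 4L,
              dimnames = list(NULL, c("CAGE", "H3K4me3", "H3K9ac", "x")))
  E[2L, 1:3] <- 0.9
  model <- structure(list(n_states = 3L, tracks = colnames(E),
                          initial = rep(1 / 3, 3), transitions = diag(3),
                          emissions = E), class = "chromatin_hmm")
  expect_equal(tss_active_state(model), 2L)
  # tie goes to the lower index
  E[3L, 1:3] <- 0.9
  model$emissions <- E
  expect_equal(tss_active_state(model), 2L)
  model$emissions <- E[, c(1L, 2L, 4L), drop = FALSE]
  model$tracks <- colnames(model$emissions)
  expect_error(tss_active_state(model), "H3K9ac")
})

test_that("a 3-state planted model is recovered from long chains", {
  E_true <- matrix(c(0.9, 0.9, 0.1,
                     0.1, 0.9, 0.8,
                     0.05, 0.05, 0.05), 3L, byrow = TRUE,
                   dimnames = list(NULL, c("CAGE", "H3K4me3", "H3K36me3")))
  T_true <- matrix(c(0.9, 0.05, 0.05,
                     0.1, 0.85, 0.05,
                     0.05, 0.05, 0.9), 3L, byrow = TRUE)
  chain <- sample_hmm_chain(rep(1 / 3, 3), T_true, E_true, 12000L,
                            seed = 61L)
  fit <- hmm_fit(chain$M, n_states = 3L, seed = 4L, n_restarts = 4L,
                 max_iter = 300L, tol = 1e-7)
  pm <- match_states(fit$emissions, E_true)
  expect_lt(max(abs(fit$emissions[pm, ] - E_true)), 0.05)
  # functional state finding on the fitted model: the CAGE+K4 state wins
  # among states emitting all three scored tracks
  colnames(fit$emissions) <- colnames(E_true)
  fit$tracks <- colnames(E_true)
  expect_silent(hmm_decode(fit, chain$M))
})
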