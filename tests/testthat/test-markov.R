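test_that("count_transitions enumerates adjacent pairs", {
  s <- encode("ab")
  m <- count_transitions(s, 1)
  expect_equal(m["a", "b"], 1)
  expect_equal(sum(m), 1)

  m2 <- count_transitions(encode("aaa"), 1)
  expect_equal(m2["a", "a"], 2)

  m3 <- count_transitions(encode("ab ab"), 1)
  expect_equal(m3["a", "b"], 2)
  expect_equal(m3["b", "space"], 1)
  expect_equal(m3["space", "a"], 1)
  expect_equal(sum(m3), 4)

  expect_error(count_transitions(encode("a", "tiny"), 1), "tiny")
})

test_that("order-2 counting uses bigram states with the documented indexing", {
  s <- encode("aba")
  m <- count_transitions(s, 2)
  expect_identical(dim(m), c(729L, 27L))
  expect_equal(m["a.b", "a"], 1)
  expect_equal(sum(m), 1)
  # total transitions = length - order
  s2 <- encode(normalize_text("the boy is falling"))
  expect_equal(sum(count_transitions(s2, 2)), length(s2) - 2L)
})

test_that("Laplace smoothing matches the closed form", {
  # empty row: uniform
  P0 <- smooth_counts(matrix(0L, 1, 27), alpha = 0.01)
  expect_equal(unname(P0[1, ]), rep(1 / 27, 27))
  # single observation: (1 + a) / (1 + 27 a)
  row <- matrix(0L, 1, 27)
  row[1, 3] <- 1L
  P1 <- smooth_counts(row, alpha = 0.01)
  expect_equal(P1[1, 3], 1.01 / 1.27)
  expect_equal(sum(P1), 1)
  # alpha = 0 reduces to MLE
  expect_equal(unname(smooth_counts(matrix(c(2, 2), 1), alpha = 0)[1, ]),
               c(0.5, 0.5))
  expect_error(smooth_counts(matrix(c(0, 0), 1), alpha = 0), "alpha")
  expect_error(smooth_counts(matrix(-1, 1, 1), 0.1), "nonnegative")
})

test_that("smoothed rows are stochastic for random count matrices", {
  set.seed(11)
  for (i in 1:100) {
    counts <- random_counts()
    P <- smooth_counts(counts, alpha = sample(alpha_grid(), 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P > 0))
  }
})

test_that("smoothing limits: uniform as alpha grows, MLE as alpha vanishes", {
  counts <- random_counts()
  counts[1, ] <- counts[1, ] + 1L  # ensure positive rows for the MLE limit
  counts <- counts + 1L
  expect_lt(max(abs(smooth_counts(counts, 1e9) - 1 / 27)), 1e-6)
  mle <- counts / rowSums(counts)
  expect_lt(max(abs(smooth_counts(counts, 1e-12) - mle)), 1e-9)
})

test_that("steady_state solves pi P = pi on hand-checked chains", {
  # 2-state toy solved by hand: pi = (5/6, 1/6)
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  pi0 <- steady_state(P)
  expect_equal(unname(pi0), c(5 / 6, 1 / 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lte(attr(pi0, "residual"), 1e-8)
  # uniform chain -> uniform stationary
  U <- matrix(1 / 27, 27, 27)
  expect_equal(unname(steady_state(U)), rep(1 / 27, 27),
               ignore_attr = TRUE)
  # any doubly stochastic chain -> uniform
  set.seed(21)
  D <- random_stochastic(5)
  for (i in 1:200) {  # Sinkhorn balancing to doubly stochastic
    D <- D / rowSums(D)
    D <- sweep(D, 2, colSums(D), "/")
  }
  D <- D / rowSums(D)
  expect_equal(unname(steady_state(D)), rep(0.2, 5), tolerance = 1e-6,
               ignore_attr = TRUE)
  # periodic two-cycle still has stationary (0.5, 0.5)
  C2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(unname(steady_state(C2)), c(0.5, 0.5), ignore_attr = TRUE)
  expect_error(steady_state(matrix(c(1, 1, 0, 1), 2)), "stochastic")
})

test_that("steady_state agrees with the matrix-power oracle", {
  set.seed(31)
  for (i in 1:100) {
    k <- sample(c(2, 3, 5, 10, 27), 1)
    P <- random_stochastic(k)
    expect_lt(max(abs(steady_state(P) - oracle_stationary(P))), 1e-8)
  }
})

test_that("char_markov composes counting and smoothing with metadata", {
  s <- encode(normalize_text("the cat sat on the mat"), "demo", "p1", "case")
  m <- char_markov(s, alpha = 0.01)
  expect_s3_class(m, "char_markov")
  expect_identical(m$k_states, 27L)
  expect_equal(sum(m$counts), length(s) - 1L)
  expect_lt(max(abs(rowSums(coef(m)) - 1)), 1e-12)
  m2 <- char_markov(s, alpha = 0.01, order = 2)
  expect_identical(m2$k_states, 729L)
})

test_that("transcript features recover the generating chain's stationary", {
  set.seed(41)
  chain <- base_chain_english()
  target <- steady_state(chain)
  s <- sample_transcript(chain, 20000, transcript_id = "long")
  pi_hat <- transcript_features(s, alpha = 0.01)
  expect_lt(mean(abs(pi_hat - target)), 0.005)
  # repeated single letter: mass ~1 on that letter
  rep_seq <- char_sequence(rep(3L, 200), "rep")
  pi_rep <- transcript_features(rep_seq, alpha = 0.01)
  expect_gt(pi_rep["c"], 0.95)
  # alternating two letters: stationary (.5, .5) on those letters
  alt <- char_sequence(rep(c(1L, 2L), 400), "alt")
  pi_alt <- transcript_features(alt, alpha = 1e-4)
  expect_equal(unname(pi_alt["a"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(pi_alt["b"]), 0.5, tolerance = 1e-3)
  expect_lt(sum(pi_alt[-(1:2)]), 1e-2)
})

test_that("order-2 stationary marginal matches the order-1 stationary", {
  set.seed(51)
  s <- sample_transcript(base_chain_english(), 4000, transcript_id = "o2")
  pi2 <- steady_state(char_markov(s, alpha = 0.01, order = 2))
  expect_lte(attr(pi2, "residual"), 1e-8)
  expect_equal(sum(pi2), 1, tolerance = 1e-10)
  marg <- colSums(matrix(pi2, 27, 27, byrow = TRUE))
  pi1 <- steady_state(char_markov(s, alpha = 0.01, order = 1))
  expect_lt(max(abs(marg - pi1)), 0.03)
})

test_that("build_feature_matrix stacks rows, excludes short transcripts", {
  corpus <- list(encode(normalize_text("the boy is falling"), "t1", "p1", "case"),
                 encode(normalize_text("water in the sink"), "t2", "p2", "control"),
                 encode("a", "t3", "p3", "case"))
  expect_warning(fm <- build_feature_matrix(corpus, alpha = 0.01), "t3")
  expect_identical(dim(fm), c(2L, 27L))
  expect_identical(fm$group, c("case", "control"))
  expect_lt(max(abs(rowSums(fm$features) - 1)), 1e-10)
  expect_error(suppressWarnings(
    build_feature_matrix(list(encode("a", "t")), 0.01)), "no transcript")
})

test_that("simulate.char_markov is reproducible and first-order only", {
  s <- encode(normalize_text("the boy on the stool reaches the jar"), "sim")
  m <- char_markov(s, alpha = 0.01)
  a <- simulate(m, nsim = 300, seed = 9)
  b <- simulate(m, nsim = 300, seed = 9)
  expect_identical(a$indices, b$indices)
  m2 <- char_markov(s, alpha = 0.01, order = 2)
  expect_error(simulate(m2, 100), "first-order")
})
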