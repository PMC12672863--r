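test_that("group chains implement the documented case-group modifications", {
  base <- base_chain_english()
  expect_lt(max(abs(rowSums(base) - 1)), 1e-12)
  expect_true(all(base > 0))

  # zero effects + no noise: case chain identical to base
  spec0 <- generator_spec(space_shift = 0, within_group_noise = Inf)
  expect_equal(make_group_chain(spec0, "case"), base)
  expect_equal(make_group_chain(spec0, "control"), base)

  # space shift raises the stationary space probability
  spec_s <- generator_spec(space_shift = 0.05, within_group_noise = Inf)
  ch_case <- make_group_chain(spec_s, "case")
  expect_lt(max(abs(rowSums(ch_case) - 1)), 1e-12)
  expect_gt(steady_state(ch_case)[27], steady_state(base)[27])

  # self-loop boost inflates diagonal mass, rows stay stochastic
  spec_b <- generator_spec(space_shift = 0, self_loop_boost = 1,
                           within_group_noise = Inf)
  ch_b <- make_group_chain(spec_b, "case")
  expect_gt(sum(diag(ch_b)), sum(diag(base)))
  expect_lt(max(abs(rowSums(ch_b) - 1)), 1e-12)

  # an invalid tilt errors
  spec_bad <- generator_spec(space_shift = -0.9, within_group_noise = Inf)
  expect_error(make_group_chain(spec_bad, "case"), "negative")
})

test_that("space matching equalises stationary space despite letter tilt", {
  spec_t <- generator_spec(space_shift = 0, letter_tilt = 0.4,
                           match_space = TRUE, within_group_noise = Inf)
  ch <- make_group_chain(spec_t, "case")
  base <- base_chain_english()
  expect_equal(steady_state(ch)[27], steady_state(base)[27],
               tolerance = 1e-6, ignore_attr = TRUE)
  # but letter stationaries differ substantially
  expect_gt(max(abs(steady_state(ch)[1:26] - steady_state(base)[1:26])), 0.01)
})

test_that("sampled transcripts follow the generating chain", {
  # deterministic 2-cycle on {a, b} yields strict alternation
  C2 <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  s <- sample_transcript(C2, 50, seed = 1)
  expect_true(all(abs(diff(s$indices)) == 1))

  # reproducibility: same seed, same transcript; different seed differs
  chain <- base_chain_english()
  a <- sample_transcript(chain, 400, seed = 5)
  b <- sample_transcript(chain, 400, seed = 5)
  d <- sample_transcript(chain, 400, seed = 6)
  expect_identical(a$indices, b$indices)
  expect_false(identical(a$indices, d$indices))

  # law of large numbers: empirical joint bigram frequencies approach the
  # chain's stationary bigram distribution
  long <- sample_transcript(chain, 50000, seed = 7)
  emp <- count_transitions(long, 1)
  joint <- steady_state(chain) * chain  # pi_i * P_ij
  expect_lt(max(abs(emp / sum(emp) - joint)), 0.005)
  expect_error(sample_transcript(chain, 1), "length")
})

test_that("generate_corpus reproduces composition, labels and determinism", {
  spec <- generator_spec(n_participants = c(case = 6L, control = 4L),
                         n_transcripts = c(case = 10L, control = 7L),
                         transcript_length = c(100L, 200L), seed = 77L)
  corp <- generate_corpus(spec)
  expect_identical(nrow(corp$manifest), 17L)
  expect_identical(sum(corp$manifest$label == "case"), 10L)
  expect_identical(length(unique(
    corp$manifest$participant_id[corp$manifest$label == "case"])), 6L)

  # byte-identical dump for an identical spec
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(corp, d1)
  write_corpus(generate_corpus(spec), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  # manifest round trip feeds the preprocessing front end
  recs <- read_transcripts(file.path(d1, "manifest.csv"))
  expect_length(recs, 17)
  expect_identical(sort(unique(vapply(recs, `[[`, "", "group"))),
                   c("case", "control"))

  expect_error(generator_spec(n_participants = c(case = 0L, control = 5L)),
               "at least one participant")
})

test_that("estimated space effect is monotone in the generator's space shift", {
  diffs <- vapply(c(0, 0.01, 0.03, 0.05), function(shift) {
    corp <- generate_corpus(generator_spec(
      n_participants = 15L, n_transcripts = NULL,
      transcripts_per_participant = 1L, transcript_length = 1500L,
      space_shift = shift, within_group_noise = Inf, seed = 202L))
    fm <- build_feature_matrix(corp$sequences, alpha = 0.01)
    sp <- fm$features[, "space"]
    mean(sp[fm$group == "case"]) - mean(sp[fm$group == "control"])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("rigidity scenario: case group has lower space-feature spread", {
  # long transcripts so across-participant heterogeneity (the Dirichlet
  # concentration contrast) dominates finite-length estimation noise
  corp <- generate_corpus(generator_spec(
    n_participants = 40L, n_transcripts = NULL,
    transcripts_per_participant = 1L, transcript_length = 1500L,
    space_shift = 0.03, self_loop_boost = 0.3,
    within_group_noise = c(case = 5000, control = 80), seed = 303L))
  fm <- build_feature_matrix(corp$sequences, alpha = 0.01)
  sp <- fm$features[, "space"]
  expect_lt(stats::sd(sp[fm$group == "case"]),
            stats::sd(sp[fm$group == "control"]))
  # and the mean is elevated
  expect_gt(mean(sp[fm$group == "case"]), mean(sp[fm$group == "control"]))
})

test_that("null corpora produce ~no Bonferroni-significant features", {
  corp <- null_corpus()
  fm <- build_feature_matrix(corp$sequences, alpha = 0.01)
  sc <- screen_features(fm)
  expect_lte(sum(sc$significant), 1)
})
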