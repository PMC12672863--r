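# Shared synthetic fixtures, built in code and cached for the test run.
# Classification-facing corpora use the generator defaults (the reference
# composition: 310 case + 242 control transcripts, lengths 300-1500), since
# the fixed-penalty Lasso operates at that sample scale; small corpora are
# used where the scale is irrelevant.

the_fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_fixtures[[key]])) the_fixtures[[key]] <- force(expr)
  the_fixtures[[key]]
}

# pure space effect at the reference composition (generator defaults)
space_corpus <- function() {
  cached("space", generate_corpus(generator_spec(seed = 101L)))
}

# transition-structured effect with the stationary space probability matched
# between groups: discriminative signal lives in letter transitions only
transition_corpus <- function() {
  cached("transition", generate_corpus(generator_spec(
    space_shift = 0, letter_tilt = 0.4, match_space = TRUE, seed = 102L)))
}

# exchangeable null at the reference composition
null_corpus_full <- function() {
  cached("null_full", generate_corpus(generator_spec(
    space_shift = 0, seed = 103L)))
}

# small exchangeable null for structural (non-classification) checks
null_corpus <- function() {
  cached("null", generate_corpus(generator_spec(
    n_participants = 40L, n_transcripts = NULL,
    transcripts_per_participant = 2L,
    transcript_length = c(400L, 800L),
    space_shift = 0, within_group_noise = 500, seed = 104L)))
}

# long-transcript space-effect corpus for the clustering property: at
# length 1500 the within-group spread is dominated by the modelled
# participant heterogeneity, not finite-length estimation noise
cluster_corpus <- function() {
  cached("cluster", generate_corpus(generator_spec(
    n_participants = 50L, n_transcripts = NULL,
    transcripts_per_participant = 2L,
    transcript_length = 1500L,
    space_shift = 0.05, within_group_noise = 500, seed = 105L)))
}

# wrap a bare feature matrix + metadata as a feature_matrix object
make_fm <- function(X, group, participant = NULL, alpha = 0.01, order = 1L) {
  n <- nrow(X)
  if (is.null(participant)) participant <- sprintf("p%03d", seq_len(n))
  if (is.null(colnames(X)))
    colnames(X) <- alphabet_names()[seq_len(ncol(X))]
  tid <- sprintf("t%03d", seq_len(n))
  rownames(X) <- tid
  structure(list(features = X, transcript_id = tid,
                 participant_id = participant, group = group,
                 alpha = alpha, order = as.integer(order)),
            class = "feature_matrix")
}

# permute group labels at the participant level, preserving the grouping
# structure for fold construction
permute_labels <- function(corpus) {
  pids <- unique(corpus$manifest$participant_id)
  plab <- corpus$manifest$label[match(pids, corpus$manifest$participant_id)]
  new_lab <- stats::setNames(sample(plab), pids)
  corpus$manifest$label <- unname(new_lab[corpus$manifest$participant_id])
  for (i in seq_along(corpus$sequences)) {
    corpus$sequences[[i]]$group <-
      unname(new_lab[corpus$sequences[[i]]$participant_id])
  }
  corpus
}

# iid null feature matrix: every row Dirichlet around the base English
# stationary, both groups from the same generator
null_feature_screen_fm <- function(n_per_group = 40L, concentration = 500) {
  pi0 <- cached("pi_base", steady_state(base_chain_english()))
  n <- 2L * n_per_group
  X <- t(vapply(seq_len(n), function(i) {
    w <- stats::rgamma(27L, shape = concentration * pi0)
    w / sum(w)
  }, numeric(27L)))
  make_fm(X, rep(c("case", "control"), each = n_per_group))
}
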