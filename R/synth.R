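the_base_chain <- new.env(parent = emptyenv())

#' Base English character-transition chain
#'
#' A 27 x 27 row-stochastic matrix with realistic English character
#' statistics, estimated (Laplace `alpha = 0.5`) from the bundled reference
#' passage `inst/extdata/base_text.txt` (an original picture-description
#' style text written for this package). Using an English-like base rather
#' than an arbitrary random chain keeps the 27 features non-exchangeable, so
#' letter-specific effects are testable.
#'
#' @param alpha Smoothing constant for the estimate (default 0.5).
#' @return 27 x 27 row-stochastic matrix with symbol dimnames.
#' @export
base_chain_english <- function(alpha = 0.5) {
  key <- paste0("a", alpha)
  if (!is.null(the_base_chain[[key]])) return(the_base_chain[[key]])
  path <- system.file("extdata", "base_text.txt", package = "charmark")
  if (path == "") path <- file.path("inst", "extdata", "base_text.txt")
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = " ")
  seq <- encode(normalize_text(txt), "base_text")
  chain <- smooth_counts(count_transitions(seq, 1L), alpha)
  the_base_chain[[key]] <- chain
  chain
}

#' Specify a synthetic transcript generator
#'
#' Describes a two-group corpus of character sequences drawn from
#' group-specific Markov chains over the 27-symbol alphabet. The control
#' group uses the base chain with per-participant Dirichlet row
#' perturbation; the case group additionally receives (in order) a
#' letter-transition tilt, an additive shift on transitions into the space
#' symbol, and a self-loop boost — emulating the elevated space usage and
#' transition rigidity reported for impaired speech. Defaults reproduce the
#' reference composition: 168 case participants contributing 310 transcripts
#' and 98 controls contributing 242, transcript lengths uniform on
#' [300, 1500] characters, Dirichlet concentration 500, and a case-group
#' space shift of 0.05.
#'
#' @param n_participants Named integer vector `c(case = , control = )`.
#' @param n_transcripts Named integer vector of total transcripts per group
#'   (each participant gets at least one; the remainder is spread randomly),
#'   or `NULL` to use `transcripts_per_participant`.
#' @param transcripts_per_participant Integer, or length-2 range, used when
#'   `n_transcripts` is `NULL`.
#' @param transcript_length Length-2 integer range (characters) or a single
#'   fixed length.
#' @param space_shift Additive tilt on each row's space-transition
#'   probability for the case group (rows renormalised; a shift driving any
#'   entry negative is an error).
#' @param self_loop_boost Case-group diagonal inflation factor: diagonal
#'   multiplied by `1 + self_loop_boost`, rows renormalised.
#' @param letter_tilt Case-group letter-to-letter tilt strength: letter
#'   columns scaled by `exp(letter_tilt * u_j)` for a fixed alternating
#'   sign pattern over the 26 letters, letter mass renormalised within each
#'   row so the row's space probability is untouched.
#' @param match_space If `TRUE`, after all case-group modifications the
#'   space column is tilted (multiplicatively, via root finding) so the case
#'   chain's stationary space probability matches the control base chain's —
#'   isolating transition structure from space usage.
#' @param within_group_noise Dirichlet concentration for per-participant row
#'   perturbation (`Inf` disables noise). A named vector
#'   `c(case = , control = )` sets groups separately; larger values mean
#'   less heterogeneity.
#' @param base_chain 27 x 27 row-stochastic base chain; default
#'   [base_chain_english()].
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return A `generator_spec` object (validated list of the above).
#' @export
generator_spec <- function(n_participants = c(case = 168L, control = 98L),
                           n_transcripts = c(case = 310L, control = 242L),
                           transcripts_per_participant = 1L,
                           transcript_length = c(300L, 1500L),
                           space_shift = 0.05,
                           self_loop_boost = 0,
                           letter_tilt = 0,
                           match_space = FALSE,
                           within_group_noise = 500,
                           base_chain = NULL,
                           seed = 1L) {
  if (is.null(base_chain)) base_chain <- base_chain_english()
  base_chain <- as.matrix(base_chain)
  k <- alphabet_size()
  stopifnot(nrow(base_chain) == k, ncol(base_chain) == k)
  validate_stochastic(base_chain)
  np <- normalize_group_param(n_participants, "n_participants")
  if (any(np < 1L)) stop("need at least one participant per group", call. = FALSE)
  if (!is.null(n_transcripts)) {
    nt <- normalize_group_param(n_transcripts, "n_transcripts")
    if (any(nt < np))
      stop("n_transcripts must be >= n_participants in each group", call. = FALSE)
  } else nt <- NULL
  noise <- normalize_group_param(within_group_noise, "within_group_noise",
                                 integer_valued = FALSE)
  if (any(noise <= 0)) stop("within_group_noise must be positive", call. = FALSE)
  if (length(transcript_length) == 1L)
    transcript_length <- rep(transcript_length, 2L)
  if (transcript_length[1L] < 2L)
    stop("transcript_length must be >= 2", call. = FALSE)
  if (self_loop_boost < 0) stop("self_loop_boost must be >= 0", call. = FALSE)
  structure(list(n_participants = np,
                 n_transcripts = nt,
                 transcripts_per_participant = as.integer(transcripts_per_participant),
                 transcript_length = as.integer(transcript_length),
                 space_shift = space_shift,
                 self_loop_boost = self_loop_boost,
                 letter_tilt = letter_tilt,
                 match_space = isTRUE(match_space),
                 within_group_noise = noise,
                 base_chain = base_chain,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

normalize_group_param <- function(x, name, integer_valued = TRUE) {
  if (length(x) == 1L) x <- c(case = unname(x), control = unname(x))
  if (!all(c("case", "control") %in% names(x)))
    stop(name, " must be a single value or named c(case = , control = )",
         call. = FALSE)
  x <- x[c("case", "control")]
  if (integer_valued) x <- stats::setNames(as.integer(x), names(x))
  x
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec>\n")
  cat("  participants: case", x$n_participants["case"],
      "/ control", x$n_participants["control"], "\n")
  if (!is.null(x$n_transcripts))
    cat("  transcripts:  case", x$n_transcripts["case"],
        "/ control", x$n_transcripts["control"], "\n")
  cat("  length range: [", x$transcript_length[1], ", ",
      x$transcript_length[2], "]\n", sep = "")
  cat("  case effects: space_shift =", x$space_shift,
      "| self_loop_boost =", x$self_loop_boost,
      "| letter_tilt =", x$letter_tilt,
      if (x$match_space) "| space-matched" else "", "\n")
  cat("  noise concentration: case", x$within_group_noise["case"],
      "/ control", x$within_group_noise["control"],
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Group-specific transition chain for one participant
#'
#' Control participants draw a Dirichlet row perturbation of the base chain;
#' case participants additionally receive the spec's letter tilt, space
#' shift and self-loop boost (and optional stationary-space matching).
#' Consumes the current RNG stream unless `participant_seed` is given.
#'
#' @param spec A `generator_spec`.
#' @param group `"case"` or `"control"`.
#' @param participant_seed Optional integer seed set before the Dirichlet
#'   draw.
#' @return 27 x 27 row-stochastic, strictly positive matrix.
#' @export
make_group_chain <- function(spec, group = c("case", "control"),
                             participant_seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  group <- match.arg(group)
  if (!is.null(participant_seed)) set.seed(participant_seed)
  P <- spec$base_chain
  if (group == "case") {
    if (spec$letter_tilt != 0) P <- apply_letter_tilt(P, spec$letter_tilt)
    if (spec$space_shift != 0) P <- apply_space_shift(P, spec$space_shift)
    if (spec$self_loop_boost > 0) P <- apply_self_loop_boost(P, spec$self_loop_boost)
    if (spec$match_space)
      P <- match_space_stationary(P, stationary_space_prob(spec$base_chain))
  }
  conc <- spec$within_group_noise[[group]]
  if (is.finite(conc)) P <- dirichlet_perturb(P, conc)
  P
}

stationary_space_prob <- function(P) {
  unname(steady_state(P)[space_index()])
}

apply_letter_tilt <- function(P, tilt) {
  k <- alphabet_size()
  L <- seq_len(k - 1L)
  u <- rep(c(1, -1), length.out = k - 1L)
  fac <- exp(tilt * u)
  letters_new <- sweep(P[, L, drop = FALSE], 2, fac, `*`)
  mass_old <- rowSums(P[, L, drop = FALSE])
  mass_new <- rowSums(letters_new)
  P[, L] <- letters_new * (mass_old / mass_new)
  P
}

apply_space_shift <- function(P, shift) {
  sp <- space_index()
  P[, sp] <- P[, sp] + shift
  if (any(P < 0))
    stop("space_shift ", shift, " drives transition probabilities negative",
         call. = FALSE)
  P / rowSums(P)
}

apply_self_loop_boost <- function(P, boost) {
  diag(P) <- diag(P) * (1 + boost)
  P / rowSums(P)
}

# multiplicative tilt on the space column so the stationary space
# probability hits `target`
match_space_stationary <- function(P, target) {
  tilt <- function(tau) {
    Q <- P
    Q[, space_index()] <- Q[, space_index()] * exp(tau)
    Q / rowSums(Q)
  }
  f <- function(tau) stationary_space_prob(tilt(tau)) - target
  root <- stats::uniroot(f, c(-4, 4), tol = 1e-10)
  tilt(root$root)
}

dirichlet_perturb <- function(P, concentration) {
  k <- ncol(P)
  out <- t(apply(P, 1, function(row) {
    w <- stats::rgamma(k, shape = concentration * row, rate = 1)
    if (all(w == 0)) row else w / sum(w)
  }))
  # keep strict positivity after perturbation
  eps <- 1e-12
  out <- out + eps
  out / rowSums(out)
}

#' Sample one transcript from a transition chain
#'
#' Draws the initial symbol from the chain's stationary distribution and
#' subsequent symbols from the chain, then post-processes to the
#' `char_sequence` normal form (space runs collapsed, flanking spaces
#' trimmed), so the realised sequence can be slightly shorter than `length`.
#'
#' @param chain 27 x 27 (or any square) row-stochastic matrix.
#' @param length Number of symbols to draw (>= 2).
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   consumed).
#' @param transcript_id,participant_id,group Metadata for the sequence.
#' @return A `char_sequence`.
#' @export
sample_transcript <- function(chain, length, seed = NULL,
                              transcript_id = "sim", participant_id = transcript_id,
                              group = "unknown") {
  chain <- as.matrix(chain)
  validate_stochastic(chain)
  length <- as.integer(length)
  if (length < 2L) stop("length must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(chain)
  cum <- t(apply(chain, 1, cumsum))
  pi0 <- steady_state(chain)
  s <- integer(length)
  u <- stats::runif(length)
  s[1L] <- min(findInterval(u[1L], cumsum(pi0)) + 1L, k)
  for (t in 2:length) {
    s[t] <- min(findInterval(u[t], cum[s[t - 1L], ]) + 1L, k)
  }
  # toy chains on k < 27 symbols yield indices over the first k letters
  char_sequence(s, transcript_id, participant_id, group)
}

#' Generate a labelled synthetic corpus
#'
#' Draws the full two-group corpus described by a [generator_spec()]: one
#' perturbed chain per participant, one or more transcripts per participant,
#' with case participants sampled from the effect-modified chain. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A `generator_spec`.
#' @return A `charmark_corpus`: list with `sequences` (list of
#'   `char_sequence`), `manifest` (data frame `transcript_id`,
#'   `label`, `participant_id`) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  sequences <- list()
  manifest <- list()
  for (group in c("case", "control")) {
    np <- spec$n_participants[[group]]
    counts <- transcripts_per_participant(spec, group, np)
    for (i in seq_len(np)) {
      pid <- sprintf("%s_%03d", group, i)
      chain <- make_group_chain(spec, group)
      for (j in seq_len(counts[i])) {
        tid <- sprintf("%s_t%02d", pid, j)
        len <- if (spec$transcript_length[1L] == spec$transcript_length[2L])
          spec$transcript_length[1L]
        else sample(spec$transcript_length[1L]:spec$transcript_length[2L], 1L)
        sequences[[length(sequences) + 1L]] <-
          sample_transcript(chain, len, transcript_id = tid,
                            participant_id = pid, group = group)
        manifest[[length(manifest) + 1L]] <-
          data.frame(transcript_id = tid, label = group, participant_id = pid,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(sequences = sequences,
                 manifest = do.call(rbind, manifest),
                 spec = spec),
            class = "charmark_corpus")
}

transcripts_per_participant <- function(spec, group, np) {
  if (!is.null(spec$n_transcripts)) {
    total <- spec$n_transcripts[[group]]
    counts <- rep(1L, np)
    extra <- total - np
    while (extra > 0L) {
      # one extra transcript each for a random set of distinct participants
      take <- min(extra, np)
      idx <- sample.int(np, take)
      counts[idx] <- counts[idx] + 1L
      extra <- extra - take
    }
    counts
  } else {
    tpp <- spec$transcripts_per_participant
    if (length(tpp) == 1L) rep(tpp, np)
    else sample(tpp[1L]:tpp[2L], np, replace = TRUE)
  }
}

#' @export
print.charmark_corpus <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat("<charmark_corpus> ", nrow(x$manifest), " transcripts (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      length(unique(x$manifest$participant_id)), " participants\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' One `.txt` file per transcript plus `manifest.csv`
#' (`path,label,participant_id`) and a `spec.json` echo of the generator
#' parameters (excluding the base chain, whose provenance is recorded as
#' its dimensions and a checksum of its values).
#'
#' @param corpus A `charmark_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "charmark_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(corpus$sequences))
  for (i in seq_along(corpus$sequences)) {
    s <- corpus$sequences[[i]]
    paths[i] <- paste0(s$transcript_id, ".txt")
    writeLines(decode(s), file.path(dir, paths[i]))
  }
  manifest <- data.frame(path = paths,
                         label = corpus$manifest$label,
                         participant_id = corpus$manifest$participant_id,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  spec <- corpus$spec
  echo <- spec[setdiff(names(spec), "base_chain")]
  echo$base_chain_dim <- dim(spec$base_chain)
  echo$base_chain_sum_check <- sum(spec$base_chain * seq_along(spec$base_chain))
  jsonlite::write_json(echo, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
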