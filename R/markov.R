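#' Count character transitions in a sequence
#'
#' For order 1, entry `(i, j)` is the number of adjacent positions where
#' symbol `i` is followed by symbol `j`; the matrix is 27 x 27. For order 2
#' the state is the preceding bigram: the matrix is 729 x 27, with the state
#' index of bigram `(c1, c2)` equal to `27 * (c1 - 1) + c2` (1-based), and
#' entry `(s, j)` counts occurrences of bigram state `s` followed by symbol
#' `j`. Total counts always equal `length(seq) - order`.
#'
#' @param seq A `char_sequence` (or bare integer index vector).
#' @param order Markov order, 1 or 2.
#' @return Integer count matrix (`k_states` x 27) with dimnames.
#' @examples
#' s <- encode(normalize_text("ab ab"), "t")
#' m <- count_transitions(s, 1)
#' m["a", "b"]  # 2
#' @export
count_transitions <- function(seq, order = 1L) {
  idx <- if (inherits(seq, "char_sequence")) seq$indices else as.integer(seq)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  k <- alphabet_size()
  n <- length(idx)
  id <- if (inherits(seq, "char_sequence")) seq$transcript_id else "<sequence>"
  if (n < order + 1L)
    stop("transcript ", id, ": sequence of length ", n,
         " too short for order ", order, " (need >= ", order + 1L, ")",
         call. = FALSE)
  if (order == 1L) {
    from <- idx[-n]
    to <- idx[-1L]
    counts <- matrix(tabulate((from - 1L) * k + to, nbins = k * k),
                     nrow = k, ncol = k, byrow = TRUE)
    dimnames(counts) <- list(alphabet_names(), alphabet_names())
  } else {
    state <- (idx[1:(n - 2L)] - 1L) * k + idx[2:(n - 1L)]
    emit <- idx[3:n]
    counts <- matrix(tabulate((state - 1L) * k + emit, nbins = k * k * k),
                     nrow = k * k, ncol = k, byrow = TRUE)
    dimnames(counts) <- list(bigram_state_names(), alphabet_names())
  }
  counts
}

bigram_state_names <- function() {
  nm <- alphabet_names()
  as.vector(t(outer(nm, nm, paste, sep = ".")))
}

#' Laplace-smooth transition counts into a row-stochastic matrix
#'
#' Applies additive smoothing over the 27 emitted symbols of each row:
#' `P[i, j] = (n[i, j] + alpha) / sum_u (n[i, u] + alpha)`. With
#' `alpha > 0` every entry is strictly positive, which makes the chain
#' irreducible and aperiodic and guarantees a unique stationary
#' distribution. With `alpha = 0` the formula reduces to the maximum
#' likelihood estimate and rows with no observations cannot be normalised
#' (an error).
#'
#' @param counts Nonnegative count matrix (`k_states` x `k_emit`).
#' @param alpha Nonnegative Laplace constant (default 0.01).
#' @return Row-stochastic matrix of the same shape.
#' @examples
#' smooth_counts(matrix(c(2, 2), 1), alpha = 0)  # 0.5 0.5
#' @export
smooth_counts <- function(counts, alpha = 0.01) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("alpha must be a single nonnegative number", call. = FALSE)
  num <- counts + alpha
  rs <- rowSums(num)
  if (any(rs == 0))
    stop("alpha = 0 with an all-zero row: transition probabilities ",
         "unnormalizable; use alpha > 0", call. = FALSE)
  num / rs
}

#' Fit a character-level Markov model to a transcript
#'
#' The package's core fitting function: counts transitions of the given
#' order in one `char_sequence`, applies Laplace smoothing with constant
#' `alpha`, and returns a classed model holding the raw counts and the
#' smoothed row-stochastic transition matrix. The stationary distribution —
#' the linguistic fingerprint used as a feature vector downstream — is
#' obtained with [steady_state()].
#'
#' @param seq A `char_sequence`.
#' @param alpha Laplace smoothing constant (default 0.01, the package's main
#'   setting; see [alpha_grid()] for the sensitivity grid).
#' @param order Markov order, 1 (27 states) or 2 (729 bigram states).
#' @return A `char_markov` object: list with `order`, `k_states`, `counts`,
#'   `alpha`, `P` (the smoothed transition matrix, `k_states` x 27) and
#'   `transcript_id`.
#' @examples
#' s <- encode(normalize_text("the cat sat on the mat"), "demo")
#' m <- char_markov(s)
#' round(coef(m)["t", "h"], 3)
#' @seealso [steady_state()], [simulate.char_markov()]
#' @export
char_markov <- function(seq, alpha = 0.01, order = 1L) {
  counts <- count_transitions(seq, order)
  P <- smooth_counts(counts, alpha)
  structure(list(order = as.integer(order),
                 k_states = nrow(P),
                 counts = counts,
                 alpha = alpha,
                 P = P,
                 transcript_id = if (inherits(seq, "char_sequence"))
                   seq$transcript_id else NA_character_),
            class = "char_markov")
}

#' @export
print.char_markov <- function(x, ...) {
  cat("<char_markov> order ", x$order, ", ", x$k_states, " states, alpha = ",
      format(x$alpha), "\n", sep = "")
  cat("  transcript: ", x$transcript_id, " (", sum(x$counts),
      " observed transitions)\n", sep = "")
  invisible(x)
}

#' @export
coef.char_markov <- function(object, ...) object$P

#' Simulate text from a fitted character-level Markov model
#'
#' Draws the initial symbol from the model's stationary distribution and
#' subsequent symbols from the transition matrix; only first-order models
#' are supported. Returns one `char_sequence` per replicate (post-processed
#' to the sequence normal form: space runs collapsed, flanking spaces
#' trimmed, so the realised length can fall slightly below `nsim` symbols).
#'
#' @param object A first-order `char_markov`.
#' @param nsim Number of symbols to draw (default 500).
#' @param seed Optional integer seed.
#' @param n Number of replicate sequences (default 1).
#' @param ... Unused.
#' @return A `char_sequence` if `n == 1`, else a list of them.
#' @export
simulate.char_markov <- function(object, nsim = 500, seed = NULL, n = 1L, ...) {
  if (object$order != 1L)
    stop("simulate() supports first-order models only", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    sample_transcript(object$P, nsim,
                      transcript_id = paste0(object$transcript_id, "_sim", i))
  })
  if (n == 1L) out[[1L]] else out
}

#' Stationary distribution of a transition model
#'
#' Solves `pi P = pi`, `sum(pi) = 1` for the unique stationary probability
#' vector of the chain. First-order models use a dense left
#' eigendecomposition (eigenvalue nearest 1; real parts taken, negatives
#' clipped at 0, renormalised) with a power-iteration fallback. Second-order
#' models use power iteration on the induced 729-state bigram chain, where
#' state `(c1, c2)` moves to `(c2, c3)` with probability `P[(c1, c2), c3]`
#' — the 729 x 729 operator is applied implicitly and never materialised.
#'
#' With `alpha > 0` the chain is strictly positive so the stationary vector
#' exists and is unique (Perron–Frobenius); for `alpha = 0` chains a
#' reducible structure is reported as an error advising `alpha > 0`.
#'
#' @param model A `char_markov`, or a bare row-stochastic square matrix.
#' @param tol Power-iteration convergence tolerance (default 1e-12).
#' @param max_iter Iteration budget (default 10000).
#' @return Named numeric vector `pi` of length `k_states`; attribute
#'   `"residual"` holds `max |pi P - pi|` (always <= 1e-8 on success).
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
#' steady_state(P)  # 5/6, 1/6
#' @export
steady_state <- function(model, tol = 1e-12, max_iter = 10000L) {
  if (inherits(model, "char_markov")) {
    if (model$order == 2L)
      return(steady_state_lifted(model$P, tol, max_iter))
    P <- model$P
  } else {
    P <- as.matrix(model)
    if (nrow(P) != ncol(P))
      stop("matrix input must be square (first-order chain)", call. = FALSE)
  }
  validate_stochastic(P)
  pi0 <- steady_state_eigen(P)
  if (is.null(pi0) || stationary_residual(pi0, P) > 1e-8)
    pi0 <- steady_state_power(P, tol, max_iter)
  res <- stationary_residual(pi0, P)
  if (res > 1e-8) {
    hint <- if (any(P == 0)) "; chain may be reducible, use alpha > 0" else ""
    stop("steady_state did not converge: residual ", format(res), hint,
         call. = FALSE)
  }
  names(pi0) <- rownames(P)
  attr(pi0, "residual") <- res
  pi0
}

validate_stochastic <- function(P) {
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix is not row-stochastic", call. = FALSE)
  invisible(P)
}

stationary_residual <- function(pi0, P) {
  max(abs(as.vector(pi0 %*% P) - pi0))
}

steady_state_eigen <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  s <- sum(v)
  if (s <= 0) return(NULL)
  v / s
}

steady_state_power <- function(P, tol = 1e-12, max_iter = 10000L) {
  k <- nrow(P)
  v <- rep(1 / k, k)
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(v %*% P)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  v
}

# stationary vector of the induced bigram chain, P being 729 x 27;
# the operator pi -> pi L is applied via a 27 x 27 reshape
steady_state_lifted <- function(P, tol = 1e-12, max_iter = 10000L) {
  k <- alphabet_size()
  if (nrow(P) != k * k || ncol(P) != k)
    stop("second-order model must have 729 x 27 transition matrix", call. = FALSE)
  validate_stochastic(P)
  step <- function(v) {
    nxt <- matrix(0, k, k)  # nxt[c2, c3]
    for (c2 in seq_len(k)) {
      rows <- seq.int(c2, by = k, length.out = k)  # states (c1, c2), c1 = 1..k
      nxt[c2, ] <- colSums(P[rows, , drop = FALSE] * v[rows])
    }
    as.vector(t(nxt))  # state id (c2 - 1) * k + c3
  }
  v <- rep(1 / (k * k), k * k)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v_new <- step(v)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  res <- max(abs(step(v) - v))
  if (!converged && res > 1e-8)
    stop("steady_state (order 2) did not converge: residual ", format(res),
         call. = FALSE)
  names(v) <- bigram_state_names()
  attr(v, "residual") <- res
  v
}

#' Stationary-distribution features for one transcript
#'
#' Composition of [count_transitions()], [smooth_counts()] and
#' [steady_state()]: the transcript's long-run character-usage fingerprint.
#'
#' @inheritParams char_markov
#' @return Named numeric vector of length 27 (order 1) or 729 (order 2)
#'   summing to 1.
#' @export
transcript_features <- function(seq, alpha = 0.01, order = 1L) {
  steady_state(char_markov(seq, alpha = alpha, order = order))
}

#' The Laplace-smoothing sensitivity grid
#'
#' The five-point grid used by [alpha_sensitivity()] to check that
#' downstream classification is stable in the smoothing constant.
#'
#' @return Numeric vector `c(0.001, 0.005, 0.01, 0.05, 0.1)`.
#' @export
alpha_grid <- function() c(0.001, 0.005, 0.01, 0.05, 0.1)

#' Build the steady-state feature matrix for a corpus
#'
#' Fits a smoothed Markov model per transcript and stacks the stationary
#' vectors: one row per transcript in input order, one column per alphabet
#' symbol (order 1) or bigram state (order 2). Transcripts too short to fit
#' (fewer than `order + 1` symbols) are excluded with a warning; if every
#' transcript fails, that is an error.
#'
#' @param corpus List of `char_sequence` objects.
#' @inheritParams char_markov
#' @return A `feature_matrix`: list with `features` (numeric matrix, rows
#'   named by transcript id), `transcript_id`, `participant_id`, `group`,
#'   `alpha`, `order`.
#' @export
build_feature_matrix <- function(corpus, alpha = 0.01, order = 1L) {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  rows <- vector("list", length(corpus))
  failed <- character(0)
  for (i in seq_along(corpus)) {
    rows[i] <- list(tryCatch(
      transcript_features(corpus[[i]], alpha = alpha, order = order),
      error = function(e) {
        failed <<- c(failed, corpus[[i]]$transcript_id)
        NULL
      }))
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("no transcript could be fitted", call. = FALSE)
  if (length(failed))
    warning("excluded ", length(failed), " transcript(s): ",
            paste(failed, collapse = ", "), call. = FALSE)
  feats <- do.call(rbind, rows[ok])
  kept <- corpus[ok]
  meta <- function(f) vapply(kept, function(s) s[[f]], character(1))
  rownames(feats) <- meta("transcript_id")
  structure(list(features = feats,
                 transcript_id = meta("transcript_id"),
                 participant_id = meta("participant_id"),
                 group = meta("group"),
                 alpha = alpha,
                 order = as.integer(order)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$features), " transcripts x ",
      ncol(x$features), " features (order ", x$order, ", alpha = ",
      format(x$alpha), ")\n", sep = "")
  tab <- table(x$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$features)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(transcript_id = x$transcript_id,
             participant_id = x$participant_id,
             group = x$group,
             x$features,
             check.names = FALSE,
             row.names = NULL)
}
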