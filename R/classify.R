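#' Participant-grouped stratified fold assignment
#'
#' Builds a cross-validation plan in which all transcripts from one
#' participant share a single fold (no subject-level leakage) while per-fold
#' class proportions stay close to the global proportion. Assignment is
#' greedy: participants are shuffled (seeded), sorted by transcript count
#' descending, and each is placed into the fold that minimises the resulting
#' class-proportion imbalance (ties: smaller fold, then lower index).
#'
#' @param x A `charmark_corpus`, `feature_matrix`, or data frame with
#'   columns `participant_id` and `label` (or `group`), one row per
#'   transcript.
#' @param n_folds Number of folds (default 5); each class must have at least
#'   `n_folds` participants.
#' @param seed Integer seed (controls the shuffle that breaks count ties).
#' @return A `fold_plan`: list with `n_folds`, `assignment` (fold index per
#'   transcript row), `participant_map` (named fold index per participant),
#'   `label` (per row).
#' @export
make_folds <- function(x, n_folds = 5L, seed = 1L) {
  meta <- corpus_meta(x)
  n_folds <- as.integer(n_folds)
  ptab <- stats::aggregate(list(n = seq_len(nrow(meta))),
                           by = list(participant = meta$participant_id,
                                     label = meta$label),
                           FUN = length)
  for (g in unique(ptab$label)) {
    if (sum(ptab$label == g) < n_folds)
      stop("class ", dQuote(g, FALSE), " has fewer than ", n_folds,
           " participants", call. = FALSE)
  }
  set.seed(seed)
  ptab <- ptab[sample.int(nrow(ptab)), , drop = FALSE]
  ptab <- ptab[order(-ptab$n), , drop = FALSE]
  classes <- unique(ptab$label)
  # transcripts per class per fold; each participant goes where their class
  # is currently scarcest, which equalises class counts (hence proportions)
  fold_class <- matrix(0, n_folds, length(classes),
                       dimnames = list(NULL, classes))
  assignment_p <- integer(nrow(ptab))
  for (i in seq_len(nrow(ptab))) {
    cl <- ptab$label[i]
    best <- order(fold_class[, cl], rowSums(fold_class), seq_len(n_folds))[1L]
    assignment_p[i] <- best
    fold_class[best, cl] <- fold_class[best, cl] + ptab$n[i]
  }
  participant_map <- stats::setNames(assignment_p, ptab$participant)
  assignment <- unname(participant_map[meta$participant_id])
  structure(list(n_folds = n_folds,
                 assignment = assignment,
                 participant_map = participant_map,
                 label = meta$label,
                 participant_id = meta$participant_id,
                 seed = seed),
            class = "fold_plan")
}

corpus_meta <- function(x) {
  if (inherits(x, "charmark_corpus")) {
    data.frame(participant_id = x$manifest$participant_id,
               label = x$manifest$label, stringsAsFactors = FALSE)
  } else if (inherits(x, "feature_matrix")) {
    data.frame(participant_id = x$participant_id, label = x$group,
               stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    lab <- if ("label" %in% names(x)) x$label else x$group
    data.frame(participant_id = x$participant_id, label = lab,
               stringsAsFactors = FALSE)
  } else stop("cannot extract participant metadata from ", class(x)[1L],
              call. = FALSE)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan>", x$n_folds, "folds,", length(x$assignment),
      "transcripts,", length(x$participant_map), "participants\n")
  tab <- table(fold = x$assignment, class = x$label)
  print(tab)
  invisible(x)
}

#' L1-penalised logistic regression: fit and predict
#'
#' Fits a Lasso logistic model on the training rows with class-balanced
#' observation weights and a fixed penalty, and returns case probabilities
#' for the test rows. The penalty is parameterised as inverse regularisation
#' strength `C` (sklearn-style): the glmnet lambda is `1 / (C * n_train)`.
#' Features enter un-standardised — steady-state probabilities share a
#' common scale.
#'
#' @param x_train,x_test Numeric feature matrices.
#' @param y_train Binary labels (0/1) for the training rows; both classes
#'   must be present.
#' @param penalty_C Inverse regularisation strength (default 1.0).
#' @param standardize Passed to glmnet (default `FALSE`).
#' @return List with `prob` (P(case) per test row) and `coef` (named
#'   coefficient vector, intercept excluded).
#' @export
fit_predict_lasso <- function(x_train, y_train, x_test, penalty_C = 1.0,
                              standardize = FALSE) {
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L)
    stop("training fold contains a single class", call. = FALSE)
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  pad <- ncol(x_train) == 1L  # glmnet requires >= 2 columns
  if (pad) {
    x_train <- cbind(x_train, `..pad` = 0)
    x_test <- cbind(x_test, `..pad` = 0)
  }
  n <- nrow(x_train)
  w <- ifelse(y_train == 1L, n / (2 * sum(y_train == 1L)),
              n / (2 * sum(y_train == 0L)))
  lambda <- 1 / (penalty_C * n)
  fit <- glmnet::glmnet(x_train, y_train, family = "binomial", alpha = 1,
                        lambda = lambda, weights = w,
                        standardize = standardize)
  prob <- as.vector(stats::predict(fit, newx = x_test, type = "response"))
  beta <- as.vector(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (pad) beta <- beta[names(beta) != "..pad"]
  list(prob = prob, coef = beta)
}

# feature representation per model variant
variant_features <- function(corpus, variant, alpha = 0.01) {
  sequences <- corpus$sequences
  k <- alphabet_size()
  switch(variant,
    charmark = build_feature_matrix(sequences, alpha = alpha, order = 1L)$features,
    second_order = build_feature_matrix(sequences, alpha = alpha, order = 2L)$features,
    freq_only = {
      X <- t(vapply(sequences, function(s)
        tabulate(s$indices, nbins = k) / length(s$indices), numeric(k)))
      colnames(X) <- alphabet_names()
      rownames(X) <- vapply(sequences, `[[`, "", "transcript_id")
      X
    },
    space_only = {
      X <- matrix(vapply(sequences, function(s)
        sum(s$indices == space_index()) / length(s$indices), numeric(1)),
        ncol = 1L, dimnames = list(
          vapply(sequences, `[[`, "", "transcript_id"), "space_prop"))
      X
    },
    stop("unknown model variant: ", variant, call. = FALSE))
}

#' Cross-validated evaluation of a model variant
#'
#' Runs the Lasso classifier under a participant-grouped fold plan for one
#' feature representation: `"charmark"` (order-1 steady states),
#' `"freq_only"` (raw character relative frequencies), `"space_only"`
#' (whitespace proportion), or `"second_order"` (order-2 bigram-state steady
#' states). Per-fold metrics (AUC, F1, precision, recall/sensitivity,
#' specificity, accuracy at threshold 0.5, Brier, ECE) are aggregated as
#' mean and SD across folds; pooled out-of-fold metrics, reliability bins,
#' optimised thresholds (Youden's J, max F1) and per-fold selected features
#' are reported alongside.
#'
#' @param corpus A `charmark_corpus` (the raw sequences are needed because
#'   the variants use different representations).
#' @param plan A `fold_plan` covering the corpus rows.
#' @param variant Model variant (see above).
#' @param alpha Laplace smoothing constant for Markov-based variants.
#' @param penalty_C Inverse regularisation strength for the Lasso.
#' @param n_bins Number of equal-width calibration bins (default 10).
#' @param standardize Z-score features using training-fold statistics only
#'   (default `FALSE`).
#' @param features Optional precomputed feature matrix for this variant
#'   (rows aligned with the corpus). Useful when the same representation is
#'   evaluated repeatedly, e.g. under label permutation; labels and folds
#'   are always taken from `corpus` and `plan`.
#' @return A `charmark_cv` object.
#' @export
evaluate_cv <- function(corpus, plan, variant = "charmark", alpha = 0.01,
                        penalty_C = 1.0, n_bins = 10L, standardize = FALSE,
                        features = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  X <- if (is.null(features)) variant_features(corpus, variant, alpha)
       else as.matrix(features)
  y <- as.integer(corpus$manifest$label == "case")
  if (nrow(X) != length(plan$assignment))
    stop("fold plan does not cover the corpus rows", call. = FALSE)
  oof <- rep(NA_real_, nrow(X))
  per_fold <- vector("list", plan$n_folds)
  selected <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    test <- plan$assignment == f
    xtr <- X[!test, , drop = FALSE]
    xte <- X[test, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- scale(xtr, mu, sg)
      xte <- scale(xte, mu, sg)
    }
    fit <- fit_predict_lasso(xtr, y[!test], xte, penalty_C = penalty_C)
    oof[test] <- fit$prob
    selected[[f]] <- names(fit$coef)[fit$coef != 0]
    m <- metrics_at_threshold(fit$prob, y[test], 0.5)
    cal <- calibration_metrics(fit$prob, y[test], n_bins)
    per_fold[[f]] <- data.frame(
      fold = f,
      auc = auc_score(fit$prob, y[test]),
      f1 = m$f1, precision = m$precision, recall = m$recall,
      specificity = m$specificity, accuracy = m$accuracy,
      brier = cal$brier, ece = cal$ece)
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), "fold")
  agg_mean <- vapply(per_fold[metric_cols], mean, numeric(1), na.rm = TRUE)
  agg_sd <- vapply(per_fold[metric_cols], stats::sd, numeric(1), na.rm = TRUE)
  pooled_cal <- calibration_metrics(oof, y, n_bins)
  pooled <- c(auc = auc_score(oof, y),
              unlist(metrics_at_threshold(oof, y, 0.5)),
              brier = pooled_cal$brier, ece = pooled_cal$ece)
  thresholds <- list(
    default = c(threshold = 0.5, unlist(metrics_at_threshold(oof, y, 0.5))),
    youden_j = threshold_report(oof, y, "youden_j"),
    f1_max = threshold_report(oof, y, "f1_max"))
  structure(list(variant = variant,
                 alpha = alpha,
                 penalty_C = penalty_C,
                 n_folds = plan$n_folds,
                 seed = plan$seed,
                 per_fold = per_fold,
                 mean = agg_mean,
                 sd = agg_sd,
                 pooled = pooled,
                 reliability = pooled_cal$reliability,
                 thresholds = thresholds,
                 selected_features = selected,
                 confusion = confusion_matrix(oof, y, 0.5),
                 oof = data.frame(transcript_id = corpus$manifest$transcript_id,
                                  participant_id = corpus$manifest$participant_id,
                                  label = y, prob = oof,
                                  fold = plan$assignment)),
            class = "charmark_cv")
}

threshold_report <- function(probs, labels, criterion) {
  opt <- optimize_threshold(probs, labels, criterion)
  c(threshold = opt$threshold, unlist(opt$metrics))
}

#' Fit and evaluate in one call
#'
#' Convenience wrapper: builds a participant-grouped stratified fold plan
#' and runs [evaluate_cv()].
#'
#' @inheritParams evaluate_cv
#' @inheritParams make_folds
#' @param x A `charmark_corpus`.
#' @param ... Passed to [evaluate_cv()].
#' @return A `charmark_cv` object.
#' @export
charmark_cv <- function(x, variant = "charmark", alpha = 0.01, n_folds = 5L,
                        seed = 1L, ...) {
  plan <- make_folds(x, n_folds = n_folds, seed = seed)
  evaluate_cv(x, plan, variant = variant, alpha = alpha, ...)
}

#' @export
print.charmark_cv <- function(x, ...) {
  cat("<charmark_cv> variant ", x$variant, " (alpha = ", format(x$alpha),
      ", C = ", format(x$penalty_C), ", ", x$n_folds, "-fold grouped CV)\n",
      sep = "")
  m <- sprintf("%.3f ± %.3f", x$mean, x$sd)
  names(m) <- names(x$mean)
  show <- c("auc", "f1", "precision", "recall", "specificity", "accuracy",
            "brier", "ece")
  print(noquote(m[show]))
  invisible(x)
}

#' @export
summary.charmark_cv <- function(object, ...) {
  cat("Cross-validated evaluation (", object$n_folds,
      " participant-grouped folds, seed ", object$seed, ")\n\n", sep = "")
  print(object)
  cat("\nPooled out-of-fold metrics:\n")
  print(round(object$pooled, 3))
  cat("\nThresholds:\n")
  for (nm in names(object$thresholds)) {
    t <- object$thresholds[[nm]]
    cat(sprintf("  %-9s thr = %.3f  F1 = %.3f  sens = %.3f  spec = %.3f\n",
                nm, t["threshold"], t["f1"], t["recall"], t["specificity"]))
  }
  cat("\nConfusion matrix at 0.5 (pooled):\n")
  print(object$confusion$counts)
  feats <- sort(table(unlist(object$selected_features)), decreasing = TRUE)
  cat("\nFeatures selected in >= half the folds: ",
      paste(names(feats)[feats >= object$n_folds / 2], collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.charmark_cv <- function(x, ...) {
  rb <- x$reliability
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey50",
                 xlab = "Mean predicted probability",
                 ylab = "Observed case fraction",
                 main = paste("Reliability curve:", x$variant), ...)
  graphics::points(rb$confidence, rb$observed, pch = 19, type = "b")
  invisible(x)
}

#' AUC of case probabilities
#'
#' Area under the ROC curve; `NA` when only one class is present.
#'
#' @param probs Predicted case probabilities.
#' @param labels Binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probs, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

metrics_at_threshold <- function(probs, labels, threshold) {
  cm <- confusion_matrix(probs, labels, threshold)$counts
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       specificity = specificity,
       accuracy = (tp + tn) / sum(cm))
}

#' Confusion matrix at a probability threshold
#'
#' Predictions are positive when `prob >= threshold`.
#'
#' @param probs Predicted case probabilities.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return List with `counts` (2 x 2: rows actual, columns predicted) and
#'   `proportions` (row-normalised).
#' @export
confusion_matrix <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  pred <- as.integer(probs >= threshold)
  counts <- matrix(0, 2, 2,
                   dimnames = list(actual = c("control", "case"),
                                   predicted = c("control", "case")))
  for (a in 0:1) for (p in 0:1)
    counts[a + 1L, p + 1L] <- sum(labels == a & pred == p)
  rs <- rowSums(counts)
  proportions <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, proportions = proportions)
}

#' Brier score, expected calibration error and reliability bins
#'
#' Brier is the mean squared error of probabilities against binary labels.
#' ECE partitions predictions into `n_bins` equal-width bins over `[0, 1]`
#' and takes the bin-count-weighted mean absolute gap between mean
#' confidence and observed positive fraction; empty bins are skipped.
#'
#' @inheritParams confusion_matrix
#' @param n_bins Number of bins (>= 2; default 10).
#' @return List with `brier`, `ece`, `reliability` (data frame: `bin`,
#'   `lower`, `upper`, `confidence`, `observed`, `count`).
#' @export
calibration_metrics <- function(probs, labels, n_bins = 10L) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  brier <- mean((probs - labels)^2)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(probs, edges, rightmost.closed = TRUE, all.inside = TRUE)
  rel <- lapply(sort(unique(bin)), function(b) {
    in_b <- bin == b
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               confidence = mean(probs[in_b]),
               observed = mean(labels[in_b]),
               count = sum(in_b))
  })
  rel <- do.call(rbind, rel)
  ece <- sum(rel$count / length(probs) * abs(rel$confidence - rel$observed))
  list(brier = brier, ece = ece, reliability = rel)
}

#' Optimise the decision threshold
#'
#' Scans candidate thresholds — midpoints between sorted unique
#' probabilities, plus 0 and 1 — and returns the one maximising the chosen
#' criterion: Youden's J (`sensitivity + specificity - 1`) or F1. Ties go to
#' the lower threshold.
#'
#' @inheritParams confusion_matrix
#' @param criterion `"youden_j"` or `"f1_max"`.
#' @return List with `threshold`, `value` (criterion value) and `metrics`
#'   (full metric set at the threshold).
#' @export
optimize_threshold <- function(probs, labels, criterion = c("youden_j", "f1_max")) {
  criterion <- match.arg(criterion)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(probs))
  cand <- sort(unique(c(0, 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)))
  score <- vapply(cand, function(thr) {
    m <- metrics_at_threshold(probs, labels, thr)
    if (criterion == "youden_j") m$recall + m$specificity - 1 else m$f1
  }, numeric(1))
  best <- which.max(score)  # first max: lowest threshold wins ties
  list(threshold = cand[best], value = score[best],
       metrics = metrics_at_threshold(probs, labels, cand[best]),
       criterion = criterion)
}

#' Smoothing-constant sensitivity sweep
#'
#' Re-runs the cross-validated evaluation over a grid of Laplace constants
#' with the classifier and fold plan held fixed, and reports the
#' max-minus-min spread of mean AUC and F1 across the grid — small spreads
#' indicate the pipeline is robust to the smoothing choice.
#'
#' @inheritParams evaluate_cv
#' @param grid Numeric vector of smoothing constants (default
#'   [alpha_grid()]).
#' @param ... Passed to [evaluate_cv()].
#' @return An `alpha_sweep`: list with `reports` (one `charmark_cv` per
#'   grid value), `table` (one row per value), `spread` (named vector:
#'   `auc`, `f1`).
#' @export
alpha_sensitivity <- function(corpus, plan, grid = alpha_grid(),
                              variant = "charmark", ...) {
  if (!length(grid)) stop("grid must be nonempty", call. = FALSE)
  reports <- lapply(grid, function(a)
    evaluate_cv(corpus, plan, variant = variant, alpha = a, ...))
  names(reports) <- format(grid)
  tab <- do.call(rbind, lapply(seq_along(grid), function(i) {
    r <- reports[[i]]
    data.frame(alpha = grid[i],
               auc = r$mean["auc"], auc_sd = r$sd["auc"],
               f1 = r$mean["f1"], f1_sd = r$sd["f1"],
               precision = r$mean["precision"], recall = r$mean["recall"],
               specificity = r$mean["specificity"],
               accuracy = r$mean["accuracy"], row.names = NULL)
  }))
  spread <- c(auc = diff(range(tab$auc)), f1 = diff(range(tab$f1)))
  structure(list(reports = reports, table = tab, spread = spread),
            class = "alpha_sweep")
}

#' @export
print.alpha_sweep <- function(x, ...) {
  cat("<alpha_sweep> over", nrow(x$table), "smoothing constants\n")
  print(x$table, digits = 3, row.names = FALSE)
  cat(sprintf("spread: AUC %.4f, F1 %.4f\n", x$spread["auc"], x$spread["f1"]))
  invisible(x)
}

#' Summary table across model variants
#'
#' Shapes a list of `charmark_cv` reports into a comparison table with
#' "mean ± SD" cells for AUC, F1, precision, recall (sensitivity),
#' specificity and accuracy.
#'
#' @param reports Named list of `charmark_cv` objects.
#' @return Data frame, one row per model.
#' @export
cv_summary_table <- function(reports) {
  fmt <- function(r, m) sprintf("%.3f ± %.3f", r$mean[m], r$sd[m])
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, AUC = fmt(r, "auc"), F1 = fmt(r, "f1"),
               Precision = fmt(r, "precision"),
               `Recall (Sens.)` = fmt(r, "recall"),
               Specificity = fmt(r, "specificity"),
               Accuracy = fmt(r, "accuracy"),
               check.names = FALSE, row.names = NULL)
  }))
}
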