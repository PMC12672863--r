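test_that("make_folds balances classes and never splits a participant", {
  # 10 participants, 5 per class, 1 transcript each: one of each per fold
  meta <- data.frame(participant_id = sprintf("p%02d", 1:10),
                     label = rep(c("case", "control"), 5))
  plan <- make_folds(meta, n_folds = 5, seed = 1)
  tab <- table(plan$assignment, plan$label)
  expect_true(all(tab == 1))

  # multi-transcript participants stay together
  meta3 <- data.frame(participant_id = rep(sprintf("p%02d", 1:12), times = 3),
                      label = rep(rep(c("case", "control"), 6), times = 3))
  plan3 <- make_folds(meta3, n_folds = 5, seed = 2)
  split_check <- tapply(plan3$assignment, plan3$participant_id,
                        function(f) length(unique(f)))
  expect_true(all(split_check == 1))

  expect_error(make_folds(meta, n_folds = 6), "fewer than")
})

test_that("fold class proportions stay within 10 points of global", {
  set.seed(33)
  for (rep in 1:20) {
    n_p <- 100
    meta <- data.frame(
      participant_id = rep(sprintf("p%03d", 1:n_p),
                           times = sample(1:4, n_p, replace = TRUE)))
    lab <- ifelse(seq_len(n_p) <= 60, "case", "control")
    meta$label <- lab[as.integer(sub("p", "", meta$participant_id))]
    plan <- make_folds(meta, n_folds = 5, seed = rep)
    p_glob <- mean(plan$label == "case")
    for (f in 1:5) {
      p_f <- mean(plan$label[plan$assignment == f] == "case")
      expect_lt(abs(p_f - p_glob), 0.10)
    }
  }
})

test_that("no participant leaks across train and test in any CV run", {
  corp <- null_corpus()
  plan <- make_folds(corp, n_folds = 5, seed = 9)
  for (f in 1:5) {
    test_p <- unique(plan$participant_id[plan$assignment == f])
    train_p <- unique(plan$participant_id[plan$assignment != f])
    expect_length(intersect(test_p, train_p), 0)
  }
})

test_that("lasso separates a separable toy and errors on one-class folds", {
  y <- rep(c(0L, 1L), each = 20)
  x <- cbind(feature = y + stats::rnorm(40, sd = 1e-3))
  fit <- fit_predict_lasso(x, y, x)
  expect_equal(auc_score(fit$prob, y), 1)
  expect_true(all(fit$prob[y == 1] > fit$prob[y == 0]))
  expect_error(fit_predict_lasso(x, rep(1L, 40), x), "single class")
})

test_that("a strong planted feature is selected across folds", {
  set.seed(43)
  n <- 200
  X <- matrix(stats::rnorm(n * 27), n, dimnames = list(NULL, alphabet_names()))
  y <- rep(c(0L, 1L), each = n / 2)
  X[, "n"] <- X[, "n"] + 2 * y
  meta <- data.frame(participant_id = sprintf("p%03d", 1:n),
                     label = ifelse(y == 1, "case", "control"))
  plan <- make_folds(meta, 5, seed = 4)
  hits <- 0
  for (f in 1:5) {
    te <- plan$assignment == f
    fit <- fit_predict_lasso(X[!te, ], y[!te], X[te, ])
    if (fit$coef["n"] != 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("AUC matches the pairwise Mann-Whitney oracle", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    labels <- stats::rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    probs <- round(stats::runif(n), sample(c(1, 3), 1))  # ties included
    expect_equal(auc_score(probs, labels), oracle_auc(probs, labels),
                 tolerance = 1e-12)
  }
})

test_that("calibration metrics match hand-computed identities", {
  labels <- rep(c(0, 1), 10)
  cal0 <- calibration_metrics(labels, labels, 10)
  expect_equal(cal0$brier, 0)
  expect_equal(cal0$ece, 0)
  cal5 <- calibration_metrics(rep(0.5, 20), labels, 10)
  expect_equal(cal5$brier, 0.25)
  expect_equal(cal5$ece, 0)
  cal8 <- calibration_metrics(rep(0.8, 20), labels, 10)
  expect_equal(cal8$ece, 0.3)
  expect_equal(nrow(cal8$reliability), 1)  # empty bins skipped
  expect_error(calibration_metrics(0.5, c(0, 1)), "equal length")
  expect_error(calibration_metrics(c(0.2, 0.4), c(0, 1), 1), "n_bins")
})

test_that("threshold optimisation scans midpoints with lower-tie wins", {
  probs <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  opt <- optimize_threshold(probs, labels, "youden_j")
  expect_gt(opt$threshold, 0.4)
  expect_lt(opt$threshold, 0.6)
  expect_equal(opt$value, 1)
  f1 <- optimize_threshold(probs, labels, "f1_max")
  expect_equal(f1$metrics$f1, 1)
  # constant probabilities: J = 0
  expect_equal(optimize_threshold(rep(0.7, 4), labels, "youden_j")$value, 0)
  expect_error(optimize_threshold(probs, c(1, 1, 1, 1)), "both classes")
})

test_that("confusion matrix counts and metric identities are consistent", {
  cm <- confusion_matrix(c(0.9, 0.1), c(0, 1), 0.5)
  expect_equal(unname(cm$counts["control", "case"]), 1)   # FP
  expect_equal(unname(cm$counts["case", "control"]), 1)   # FN
  expect_equal(unname(cm$counts["case", "case"]), 0)
  # 4-row worked case: probs vs labels enumerated by hand
  probs <- c(0.2, 0.6, 0.7, 0.3)
  labels <- c(0, 0, 1, 1)
  cm4 <- confusion_matrix(probs, labels, 0.5)
  expect_equal(as.vector(cm4$counts), c(1, 1, 1, 1))  # TN, FN, FP, TP
  m <- charmark:::metrics_at_threshold(probs, labels, 0.5)
  tp <- cm4$counts["case", "case"]; tn <- cm4$counts["control", "control"]
  expect_equal(m$accuracy, unname(tp + tn) / 4)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$recall, unname(tp) / sum(cm4$counts["case", ]))
  rowsums <- rowSums(cm4$proportions)
  expect_equal(unname(rowsums), c(1, 1))
  expect_error(confusion_matrix(probs, labels, 1.5), "threshold")
})

test_that("evaluate_cv covers every row once and reports coherent metrics", {
  corp <- space_corpus()
  plan <- make_folds(corp, 5, seed = 7)
  cv <- evaluate_cv(corp, plan, "charmark")
  expect_s3_class(cv, "charmark_cv")
  expect_false(anyNA(cv$oof$prob))
  expect_identical(nrow(cv$oof), length(corp$sequences))
  rates <- cv$mean[c("f1", "precision", "recall", "specificity", "accuracy")]
  expect_true(all(rates >= 0 & rates <= 1))
  expect_true(all(cv$sd >= 0, na.rm = TRUE))
  expect_gte(cv$mean["brier"], 0); expect_lte(cv$mean["brier"], 1)
  expect_gte(cv$mean["ece"], 0); expect_lte(cv$mean["ece"], 1)
  # the planted space effect is learnable
  expect_gt(cv$mean["auc"], 0.8)
  expect_error(evaluate_cv(corp, plan, "nonsense"), "unknown model variant")
})

test_that("variant representations have the documented shapes", {
  corp <- null_corpus()
  n <- length(corp$sequences)
  expect_identical(dim(charmark:::variant_features(corp, "charmark")),
                   c(n, 27L))
  expect_identical(dim(charmark:::variant_features(corp, "freq_only")),
                   c(n, 27L))
  expect_identical(dim(charmark:::variant_features(corp, "space_only")),
                   c(n, 1L))
  # whitespace proportion definition: space count over sequence length
  sp <- charmark:::variant_features(corp, "space_only")[1, 1]
  s1 <- corp$sequences[[1]]
  expect_equal(sp, sum(s1$indices == 27) / length(s1$indices))
})

test_that("alpha sweep holds folds fixed and reports spreads", {
  corp <- space_corpus()
  plan <- make_folds(corp, 5, seed = 7)
  one <- alpha_sensitivity(corp, plan, grid = 0.01)
  expect_equal(unname(one$spread), c(0, 0))
  expect_error(alpha_sensitivity(corp, plan, grid = numeric(0)), "nonempty")
  # enormous smoothing flattens features to uniform: chance-level AUC
  flat <- evaluate_cv(corp, plan, "charmark", alpha = 1e6)
  expect_lt(abs(flat$mean["auc"] - 0.5), 0.05)
})
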