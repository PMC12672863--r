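#' K-means clustering with silhouette model selection
#'
#' Runs seeded k-means (10 restarts) on the steady-state vectors for each
#' candidate `k`, scores each solution by mean silhouette width (Euclidean
#' distance), and returns the clustering for the silhouette-optimal `k`
#' (ties go to the smaller `k`). Clustering is done in the full feature
#' space; PCA is used only for display (see [pca_project()]).
#'
#' @param fm A `feature_matrix` (or bare numeric matrix) with >= 3 rows; all
#'   rows identical is a degenerate input and an error.
#' @param k_range Candidate cluster counts, a subset of `2..(rows - 1)`.
#' @param seed Integer seed.
#' @return A `charmark_clustering`: list with `k`, `assignments`,
#'   `silhouette`, `silhouette_by_k`, `label_agreement` (max-over-matchings
#'   accuracy against group labels, `NA` when labels are absent or all
#'   `"unknown"`).
#' @export
cluster_kmeans <- function(fm, k_range = 2:6, seed = 1L) {
  X <- if (inherits(fm, "feature_matrix")) fm$features else as.matrix(fm)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows to cluster", call. = FALSE)
  if (all(apply(X, 2, function(col) diff(range(col)) == 0)))
    stop("degenerate input: all rows identical, silhouette undefined",
         call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within 2..(rows - 1)", call. = FALSE)
  d <- stats::dist(X)
  sil <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(seed)
    fits[[i]] <- stats::kmeans(X, centers = k_range[i], nstart = 10L,
                               iter.max = 100L)
    sw <- cluster::silhouette(fits[[i]]$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)  # which.max takes the first maximum: smaller k wins ties
  fit <- fits[[best]]
  agreement <- NA_real_
  if (inherits(fm, "feature_matrix") && length(unique(fm$group)) == 2L)
    agreement <- label_agreement(fit$cluster, fm$group)
  structure(list(k = k_range[best],
                 assignments = fit$cluster,
                 silhouette = sil[best],
                 silhouette_by_k = stats::setNames(sil, k_range),
                 label_agreement = agreement,
                 withinss = fit$tot.withinss,
                 seed = seed),
            class = "charmark_clustering")
}

# max-over-permutations accuracy vs true binary groups; for k = 2 the two
# label swaps are enumerated, for k > 2 each cluster claims its majority
# label (purity-style matching)
label_agreement <- function(assignments, groups) {
  tab <- table(assignments, groups)
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / length(groups)
  } else {
    sum(apply(tab, 1, max)) / length(groups)
  }
}

#' @export
print.charmark_clustering <- function(x, ...) {
  cat("<charmark_clustering> k =", x$k,
      "| mean silhouette =", round(x$silhouette, 3), "\n")
  cat("  silhouette by k:",
      paste(names(x$silhouette_by_k), round(x$silhouette_by_k, 3),
            sep = ":", collapse = "  "), "\n")
  if (!is.na(x$label_agreement))
    cat("  agreement with group labels:", round(x$label_agreement, 3), "\n")
  invisible(x)
}

#' Two-dimensional PCA projection of the feature matrix
#'
#' Principal components of the mean-centred (not variance-scaled)
#' steady-state vectors: the features share a common probability scale, so
#' unit-variance scaling would only inflate rare-letter noise. Component
#' signs follow a deterministic convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param fm A `feature_matrix` (or numeric matrix) with >= 3 rows and rank
#'   >= 2 after centring.
#' @return A `charmark_pca`: list with `scores` (n x 2), `loadings`
#'   (p x 2), `explained_variance_ratio` (length 2), `group`.
#' @export
pca_project <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$features else as.matrix(fm)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # a single varying direction still projects (second axis carries 0
  # variance); only rank-0 data (all rows identical up to centring) is
  # degenerate
  if (length(pc$sdev) < 2L || pc$sdev[1L] < 1e-12)
    stop("feature matrix has rank 0 after centring: no variation to project",
         call. = FALSE)
  flip <- vapply(1:2, function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, 1:2, drop = FALSE], 2, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores,
                 loadings = loadings,
                 explained_variance_ratio = evr[1:2],
                 group = if (inherits(fm, "feature_matrix")) fm$group else NULL),
            class = "charmark_pca")
}

#' @export
print.charmark_pca <- function(x, ...) {
  cat("<charmark_pca>", nrow(x$scores), "transcripts; explained variance",
      paste(round(x$explained_variance_ratio, 3), collapse = " + "), "\n")
  invisible(x)
}

#' @export
plot.charmark_pca <- function(x, ...) {
  col <- if (is.null(x$group)) "black" else
    c(case = "firebrick", control = "steelblue",
      unknown = "grey40")[x$group]
  graphics::plot(x$scores, col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance_ratio[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance_ratio[2]),
                 ...)
  if (!is.null(x$group))
    graphics::legend("topright", legend = unique(x$group), pch = 19,
                     col = c(case = "firebrick", control = "steelblue",
                             unknown = "grey40")[unique(x$group)])
  invisible(x)
}

#' Rolling mean and standard deviation of a feature series
#'
#' Sliding-window summaries used to inspect how a single feature (typically
#' the space character's stationary probability) drifts across transcript
#' indices: elevated means with reduced variance indicate more rigid, less
#' adaptive usage.
#'
#' @param values Numeric series.
#' @param window Window width, between 2 and `length(values)`.
#' @return List with `means` and `sds` (sample SD, denominator `n - 1`),
#'   each of length `length(values) - window + 1`.
#' @examples
#' rolling_stats(c(1, 2, 3, 4), 2)$means  # 1.5 2.5 3.5
#' @export
rolling_stats <- function(values, window) {
  n <- length(values)
  window <- as.integer(window)
  if (window < 2L || window > n)
    stop("window must lie in [2, length(values)]", call. = FALSE)
  starts <- seq_len(n - window + 1L)
  means <- vapply(starts, function(i) mean(values[i:(i + window - 1L)]), numeric(1))
  sds <- vapply(starts, function(i) stats::sd(values[i:(i + window - 1L)]), numeric(1))
  list(means = means, sds = sds)
}
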