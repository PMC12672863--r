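#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup_x |F_x(x) - F_y(x)|`, the maximal distance between the
#' two empirical cumulative distribution functions, with a p-value from the
#' asymptotic two-sample Kolmogorov distribution at effective sample size
#' `n_x * n_y / (n_x + n_y)`. A seeded permutation p-value is available for
#' small samples.
#'
#' @param x,y Nonempty numeric samples.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List with elements `statistic` (D) and `p_value`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic  # 1/3
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("samples must be nonempty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  D <- unname(kt$statistic)
  if (method == "asymptotic") {
    p <- unname(kt$p.value)
  } else {
    set.seed(seed)
    pooled <- c(x, y)
    nx <- length(x)
    stats_perm <- replicate(n_perm, {
      idx <- sample.int(length(pooled), nx)
      unname(suppressWarnings(
        stats::ks.test(pooled[idx], pooled[-idx], exact = FALSE))$statistic)
    })
    p <- (1 + sum(stats_perm >= D - 1e-12)) / (n_perm + 1)
  }
  list(statistic = D, p_value = p)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order preserved; controls family-wise error
#' across the `m` screened features.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests (must be at least `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("m must be >= number of tests", call. = FALSE)
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Screen character features for group differences
#'
#' Runs a two-sample KS test per feature column between the two groups and
#' applies Bonferroni correction with `m = ncol` — the full character set,
#' including constant columns. Results are sorted by `D` descending, ties
#' broken alphabetically by feature name. Significance means
#' `p_adjusted < level`.
#'
#' @param fm A `feature_matrix` (each group needs >= 2 rows).
#' @param group_a,group_b Group labels to compare (defaults `"case"` vs
#'   `"control"`).
#' @param level Family-wise significance level (default 0.05).
#' @param method Passed to [ks_two_sample()].
#' @return A `ks_screen` data frame with columns `feature`, `D`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
screen_features <- function(fm, group_a = "case", group_b = "control",
                            level = 0.05, method = "asymptotic") {
  stopifnot(inherits(fm, "feature_matrix"))
  for (g in c(group_a, group_b)) {
    if (sum(fm$group == g) < 2L)
      stop("group ", dQuote(g, FALSE), " needs at least 2 rows", call. = FALSE)
  }
  X <- fm$features
  a <- fm$group == group_a
  b <- fm$group == group_b
  res <- lapply(seq_len(ncol(X)), function(j) {
    ks <- ks_two_sample(X[a, j], X[b, j], method = method)
    data.frame(feature = colnames(X)[j],
               D = ks$statistic,
               p_value = ks$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni_adjust(out$p_value, m = ncol(X))
  out$significant <- out$p_adjusted < level
  out <- out[order(-out$D, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ks_screen", "data.frame")
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "level") <- level
  out
}

#' @export
print.ks_screen <- function(x, n = 10L, ...) {
  g <- attr(x, "groups")
  cat("Kolmogorov-Smirnov feature screen: ", g[1L], " vs ", g[2L],
      " (Bonferroni, level ", format(attr(x, "level")), ")\n", sep = "")
  cat(sum(x$significant), "of", nrow(x), "features significant\n\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Write a KS screen result to CSV or JSON
#'
#' @param x A `ks_screen`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_screen <- function(x, path) {
  stopifnot(inherits(x, "ks_screen"))
  df <- as.data.frame(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
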