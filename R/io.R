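#' Write and read feature matrices as CSV
#'
#' The CSV carries `transcript_id`, `participant_id`, `group`, then one
#' column per feature (the space symbol serialised as `"space"`).
#' Probabilities are written with 12 significant digits, which makes the
#' write/read round trip exact at that formatting.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path` invisibly (writer); a `feature_matrix` (reader).
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @param alpha,order Metadata to attach on read (the CSV itself does not
#'   store them); defaults `NA`.
#' @export
read_features <- function(path, alpha = NA_real_, order = 1L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("transcript_id", "participant_id", "group")
  if (!all(meta_cols %in% names(df)))
    stop("feature CSV must start with transcript_id, participant_id, group",
         call. = FALSE)
  feats <- as.matrix(df[setdiff(names(df), meta_cols)])
  rownames(feats) <- df$transcript_id
  structure(list(features = feats,
                 transcript_id = df$transcript_id,
                 participant_id = df$participant_id,
                 group = df$group,
                 alpha = alpha,
                 order = as.integer(order)),
            class = "feature_matrix")
}

#' Export a transition network for visualisation
#'
#' Writes the first-order transition structure as a directed graph: 27
#' nodes (space rendered as `"␣"`), one edge per transition with
#' probability at least `prune_threshold`, self-loops included, nodes and
#' edges in fixed alphabet order. Formats: Graphviz DOT (edge `penwidth`
#' scaled by probability), a plain `from,to,probability` edge CSV, or
#' GraphML.
#'
#' @param model A first-order `char_markov` (or bare 27 x 27 row-stochastic
#'   matrix).
#' @param path Output file path.
#' @param prune_threshold Minimum transition probability for an edge to be
#'   retained (default 0, the complete digraph).
#' @param format `"dot"`, `"edge_csv"` or `"graphml"`.
#' @return Invisible data frame of the retained edges.
#' @export
export_network <- function(model, path, prune_threshold = 0,
                           format = c("dot", "edge_csv", "graphml")) {
  format <- match.arg(format)
  P <- if (inherits(model, "char_markov")) {
    if (model$order != 1L)
      stop("network export supports first-order models only", call. = FALSE)
    model$P
  } else as.matrix(model)
  k <- alphabet_size()
  stopifnot(nrow(P) == k, ncol(P) == k)
  validate_stochastic(P)
  sym <- c(letters, "␣")
  idx <- which(P >= prune_threshold, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  edges <- data.frame(from = sym[idx[, 1L]],
                      to = sym[idx[, 2L]],
                      probability = P[idx],
                      stringsAsFactors = FALSE)
  pfmt <- function(p) formatC(p, digits = 12, format = "g")
  lines <- switch(format,
    dot = c("digraph transitions {",
            paste0("  \"", sym, "\";"),
            sprintf("  \"%s\" -> \"%s\" [weight=%s, penwidth=%.2f];",
                    edges$from, edges$to, pfmt(edges$probability),
                    0.5 + 4 * edges$probability),
            "}"),
    edge_csv = c("from,to,probability",
                 sprintf("%s,%s,%s", edges$from, edges$to,
                         pfmt(edges$probability))),
    graphml = c('<?xml version="1.0" encoding="UTF-8"?>',
                '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
                '  <key id="p" for="edge" attr.name="probability" attr.type="double"/>',
                '  <graph id="transitions" edgedefault="directed">',
                sprintf('    <node id="%s"/>', sym),
                sprintf('    <edge source="%s" target="%s"><data key="p">%s</data></edge>',
                        edges$from, edges$to, pfmt(edges$probability)),
                "  </graph>", "</graphml>"))
  writeLines(lines, path, useBytes = FALSE)
  invisible(edges)
}

#' Write a cross-validation report as JSON
#'
#' Serialises a `charmark_cv` (config echo, per-fold and aggregate metrics,
#' thresholds, reliability bins, selected features, pooled confusion
#' counts) for downstream tooling.
#'
#' @param report A `charmark_cv`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "charmark_cv"))
  out <- list(
    config = list(variant = report$variant, alpha = report$alpha,
                  penalty_C = report$penalty_C, n_folds = report$n_folds,
                  seed = report$seed),
    per_fold = report$per_fold,
    mean = as.list(report$mean),
    sd = as.list(report$sd),
    pooled = as.list(report$pooled),
    thresholds = lapply(report$thresholds, as.list),
    reliability = report$reliability,
    selected_features = report$selected_features,
    confusion_counts = as.data.frame(as.table(report$confusion$counts)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
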