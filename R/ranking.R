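## Ranking of the aggregated selected gene set: by cross-validation selection
## frequency, or by mean weighted information gain over an entropy-criterion
## random forest whose every internal node is recorded.

## natural order for gene ids: alphabetic prefix, then numeric suffix
.gene_id_rank <- function(ids) {
  pre <- sub("([0-9]+)$", "", ids)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", ids)))
  num[!grepl("[0-9]$", ids)] <- NA
  order(order(pre, num, ids, na.last = TRUE))
}

## shared sort stage: rank ids by descending score, ties by descending
## tie_score (if given), then natural gene id order
.rank_stage <- function(gene_ids, scores, method, tie_scores = NULL) {
  stopifnot(length(gene_ids) == length(scores))
  ts <- if (is.null(tie_scores)) rep(0, length(gene_ids)) else tie_scores
  ts[is.na(ts)] <- -Inf
  o <- order(-scores, -ts, .gene_id_rank(gene_ids))
  out <- data.frame(rank = seq_along(o), gene_id = gene_ids[o],
                    score = scores[o], stringsAsFactors = FALSE)
  class(out) <- c("ranked_genes", "data.frame")
  attr(out, "method") <- method
  out
}

#' Rank genes from precomputed scores
#'
#' The shared sort stage behind [rank_by_frequency()] and [rank_by_forest()]:
#' descending score, ties broken by descending `tie_scores` (when supplied,
#' e.g. mean training-fold relevance) and then by gene id in natural order.
#'
#' @param gene_ids Character vector of gene ids.
#' @param scores Numeric scores, one per gene.
#' @param method Label stored on the result (e.g. `"MGS_f"`, `"MGS_rf"`).
#' @param tie_scores Optional numeric tie-break scores.
#' @return A `ranked_genes` data.frame with columns `rank`, `gene_id`, `score`.
#' @export
rank_genes <- function(gene_ids, scores, method = "scores", tie_scores = NULL) {
  .rank_stage(gene_ids, scores, method, tie_scores)
}

#' Aggregate per-fold selections into the union set
#'
#' @param selections A list of `mgs_selection` objects and/or character
#'   vectors of gene ids (one element per cross-validation fold).
#' @return Object of class `mgs_union`: data.frame with columns `gene_id`,
#'   `freq` (number of folds selecting the gene) and `mean_score` (mean
#'   selection score over those folds; `NA` for plain id vectors), in order
#'   of first appearance. Attribute `n_folds`.
#' @examples
#' u <- union_selections(list(c("g1", "g3", "g4", "g5", "g6"),
#'                            c("g1", "g2", "g4", "g6")))
#' u$freq   # 2 1 2 1 2 1 for g1,g3,g4,g5,g6,g2
#' @export
union_selections <- function(selections) {
  if (!is.list(selections) || length(selections) == 0)
    stop("need at least one fold selection")
  ids <- lapply(selections, function(s) {
    if (inherits(s, "mgs_selection")) s$selected$gene_id else as.character(s)
  })
  scores <- lapply(selections, function(s) {
    if (inherits(s, "mgs_selection")) s$selected$score
    else rep(NA_real_, length(s))
  })
  if (all(lengths(ids) == 0)) stop("all fold selections are empty")
  all_ids <- unlist(ids)
  all_scores <- unlist(scores)
  uniq <- unique(all_ids)
  freq <- vapply(uniq, function(g)
    sum(vapply(ids, function(v) g %in% v, TRUE)), 0L)
  mean_score <- vapply(uniq, function(g) {
    v <- all_scores[all_ids == g]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  out <- data.frame(gene_id = uniq, freq = unname(freq),
                    mean_score = unname(mean_score), stringsAsFactors = FALSE)
  class(out) <- c("mgs_union", "data.frame")
  attr(out, "n_folds") <- length(selections)
  out
}

#' Frequency-based ranking of the union set
#'
#' Relative frequency `P(S_i) = F_i / N_union`, where `F_i` counts the folds
#' in which gene `i` was selected and `N_union` is the size of the union set;
#' genes are ranked by descending `P`.
#'
#' @param counts An `mgs_union` from [union_selections()].
#' @param n_union Denominator; defaults to `nrow(counts)`.
#' @return A `ranked_genes` data.frame (method `"MGS_f"`) whose `score` holds
#'   the relative frequencies.
#' @export
rank_by_frequency <- function(counts, n_union = nrow(counts)) {
  stopifnot(nrow(counts) > 0, n_union > 0)
  .rank_stage(counts$gene_id, counts$freq / n_union, "MGS_f",
              tie_scores = counts$mean_score)
}

#' Class entropy in bits
#'
#' `H = -sum_i p_i log2 p_i` over the empirical class proportions.
#'
#' @param labels Discrete vector of class labels.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  .entropy_counts(table(labels))
}

#' Weighted information gain of a node split
#'
#' `IG = (N_t/N) * [H(parent) - (N_L/N_t) H(left) - (N_R/N_t) H(right)]`
#' with entropies in bits: the entropy reduction of the split, weighted by
#' the fraction of all samples reaching the node.
#'
#' @param parent_labels Labels of the samples at the node.
#' @param left_labels,right_labels Labels of the two children; together they
#'   must partition the parent.
#' @param n_total Total number of samples in the tree's data (`N`).
#' @return Weighted information gain in bits (non-negative for an optimal
#'   split).
#' @export
weighted_information_gain <- function(parent_labels, left_labels, right_labels,
                                      n_total) {
  nt <- length(parent_labels)
  if (nt == 0) stop("empty parent node")
  nl <- length(left_labels); nr <- length(right_labels)
  if (nl + nr != nt ||
      !identical(sort(as.character(c(left_labels, right_labels))),
                 sort(as.character(parent_labels))))
    stop("left and right children must partition the parent")
  if (n_total < nt) stop("n_total must be at least the parent size")
  hl <- if (nl > 0) entropy_bits(left_labels) else 0
  hr <- if (nr > 0) entropy_bits(right_labels) else 0
  (nt / n_total) *
    (entropy_bits(parent_labels) - (nl / nt) * hl - (nr / nt) * hr)
}

## best threshold split of one feature by entropy reduction; O(n log n)
## returns NULL when no threshold strictly reduces entropy
.best_split <- function(x, y_int, K) {
  o <- order(x)
  xs <- x[o]; ys <- y_int[o]
  n <- length(xs)
  cum <- apply(outer(ys, seq_len(K), function(a, b) a == b), 2, cumsum)
  cut_ok <- which(xs[-n] < xs[-1])          # splits only between distinct values
  if (!length(cut_ok)) return(NULL)
  nl <- cut_ok
  cl <- cum[cut_ok, , drop = FALSE]
  cr <- rep(cum[n, ], each = length(cut_ok)) - cl
  dim(cr) <- dim(cl)
  plog <- function(p) ifelse(p > 0, p * log2(p), 0)
  hl <- -rowSums(plog(cl / nl))
  hr <- -rowSums(plog(cr / (n - nl)))
  hp <- .entropy_counts(cum[n, ])
  gain <- hp - (nl / n) * hl - ((n - nl) / n) * hr
  b <- which.max(gain)
  if (gain[b] <= 1e-12) return(NULL)
  list(threshold = (xs[cut_ok[b]] + xs[cut_ok[b] + 1]) / 2, gain = gain[b])
}

## grow one entropy-criterion tree on a bootstrap sample, recording every
## internal node's (feature, weighted IG); recursion by explicit stack
.grow_ig_tree <- function(X, y_int, K, mtry, n_total) {
  rec_g <- integer(0); rec_ig <- numeric(0)
  stack <- list(seq_len(nrow(X)))
  while (length(stack)) {
    idx <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(idx) < 2 || length(unique(y_int[idx])) < 2) next
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- .best_split(X[idx, f], y_int[idx], K)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) next
    left <- idx[X[idx, best_f] <= best$threshold]
    right <- idx[X[idx, best_f] > best$threshold]
    rec_g <- c(rec_g, best_f)
    rec_ig <- c(rec_ig, (length(idx) / n_total) * best$gain)
    stack[[length(stack) + 1L]] <- left
    stack[[length(stack) + 1L]] <- right
  }
  list(gene = rec_g, ig = rec_ig)
}

#' Forest-based ranking by mean weighted information gain
#'
#' Fits a random forest of entropy-criterion decision trees (bootstrap
#' samples, random feature subsets) on the dataset restricted to the union
#' gene set, records every internal node's gene and weighted information gain
#' ([weighted_information_gain()]), and scores each gene by the *mean*
#' weighted gain over the nodes that split on it. Genes never split on score
#' 0. The forest here is purpose-built so that the per-node gains are exactly
#' the entropy-reduction quantity being averaged; it is distinct from the
#' random-forest *classifier* used in evaluation.
#'
#' @param ds A complete [expression_dataset()].
#' @param genes Character vector of gene ids to rank (the union set); defaults
#'   to all genes in `ds`.
#' @param n_trees Number of trees `M` (default 300).
#' @param mtry Features sampled per node; default `ceiling(sqrt(#genes))`.
#' @param seed RNG seed (required: scores are reproducible bit-for-bit given
#'   the seed).
#' @param tie_scores Optional named tie-break scores (e.g. mean relevance).
#' @return A `ranked_genes` data.frame (method `"MGS_rf"`); attribute
#'   `node_records` holds every recorded `(gene_id, weighted_ig)` pair.
#' @export
rank_by_forest <- function(ds, genes = ds$gene_ids, n_trees = 300,
                           mtry = NULL, seed, tie_scores = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), n_trees >= 1)
  if (missing(seed)) stop("seed is required")
  if (length(unique(ds$labels)) < 2) stop("labels have a single class")
  gi <- match(genes, ds$gene_ids)
  if (anyNA(gi)) stop("unknown gene id: ", paste(genes[is.na(gi)], collapse = ", "))
  X <- t(ds$expression[gi, , drop = FALSE])
  y_int <- as.integer(factor(ds$labels))
  K <- max(y_int)
  n <- nrow(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  set.seed(seed)
  rec_g <- integer(0); rec_ig <- numeric(0)
  for (m in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    tr <- .grow_ig_tree(X[boot, , drop = FALSE], y_int[boot], K, mtry, n)
    rec_g <- c(rec_g, tr$gene)
    rec_ig <- c(rec_ig, tr$ig)
  }
  score <- numeric(length(genes))
  if (length(rec_g)) {
    agg <- tapply(rec_ig, rec_g, mean)
    score[as.integer(names(agg))] <- agg
  }
  ts <- if (!is.null(tie_scores)) unname(tie_scores[genes]) else NULL
  out <- .rank_stage(genes, score, "MGS_rf", tie_scores = ts)
  attr(out, "node_records") <- data.frame(
    gene_id = genes[rec_g], weighted_ig = rec_ig, stringsAsFactors = FALSE)
  out
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat("ranked_genes (", attr(x, "method"), "): ", nrow(x), " genes\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Top-eta biomarker panel
#'
#' @param ranked A `ranked_genes` data.frame.
#' @param eta Panel size; when fewer genes are available the whole list is
#'   returned.
#' @return Character vector of the first `min(eta, nrow)` gene ids.
#' @export
top_eta <- function(ranked, eta) {
  stopifnot(eta >= 1)
  ranked$gene_id[seq_len(min(eta, nrow(ranked)))]
}

#' Write a ranked gene list as TSV
#'
#' @param ranked A `ranked_genes` data.frame.
#' @param path Output TSV path (columns rank, gene_id, score, method).
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranked, path) {
  out <- data.frame(ranked, method = attr(ranked, "method"))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
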