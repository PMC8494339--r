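## Cross-validated evaluation harness: nested per-fold selection and ranking
## on training data only, top-eta panel, classifier fit/predict, accuracy and
## AUROC.

#' Build cross-validation folds
#'
#' Leave-one-out when the sample count is below `loocv_threshold` (default
#' 100), otherwise stratified `k`-fold: samples are shuffled within class and
#' dealt round-robin so every fold keeps both classes.
#'
#' @param labels Per-sample class labels (any discrete vector).
#' @param seed RNG seed used for the stratified shuffle (ignored for LOOCV).
#' @param k Number of folds for the large-sample case (default 10).
#' @param loocv_threshold Sample count below which LOOCV is used (default 100).
#' @return A list of integer test-index vectors partitioning `1..n`;
#'   attribute `scheme` is `"LOOCV"` or `"KFCV"`.
#' @export
make_folds <- function(labels, seed = 1, k = 10, loocv_threshold = 100) {
  n <- length(labels)
  if (n < 2) stop("need at least 2 samples")
  if (n < loocv_threshold) {
    folds <- as.list(seq_len(n))
    attr(folds, "scheme") <- "LOOCV"
    return(folds)
  }
  set.seed(seed)
  fold_of <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- split(seq_len(n), fold_of)
  names(folds) <- NULL
  attr(folds, "scheme") <- "KFCV"
  folds
}

#' Confusion counts for binary predictions
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param positive The label value counted as positive.
#' @return List with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  stopifnot(length(truth) == length(predicted))
  p <- truth == positive
  pp <- predicted == positive
  list(TP = sum(p & pp), TN = sum(!p & !pp),
       FP = sum(!p & pp), FN = sum(p & !pp))
}

#' True- and false-positive rates
#'
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`. A zero denominator yields `NaN`,
#' flagging the rate as undefined rather than silently zero.
#'
#' @param counts A list with fields `TP`, `TN`, `FP`, `FN`
#'   (see [confusion_counts()]).
#' @return Named numeric vector `c(TPR=, FPR=)`.
#' @export
tpr_fpr <- function(counts) {
  c(TPR = counts$TP / (counts$TP + counts$FN),
    FPR = counts$FP / (counts$FP + counts$TN))
}

#' Area under the ROC curve
#'
#' Computed by the midrank (Mann-Whitney) formula: the probability that a
#' random positive scores above a random negative, ties counting one half —
#' identical to the area under the TPR-vs-FPR curve over all thresholds.
#'
#' @param scores Numeric classifier scores, higher meaning more positive.
#' @param labels Binary labels (the larger sorted value is the positive
#'   class), or logical.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == max(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## fit a classifier on training data, return scores and predicted labels for
## the test matrix; positive class = code 1
.fit_predict <- function(Xtr, ytr, Xte, classifier, n_trees, seed) {
  ytr_f <- factor(ytr, levels = sort(unique(ytr)))
  pos <- levels(ytr_f)[length(levels(ytr_f))]
  if (classifier == "svm") {
    fit <- e1071::svm(Xtr, ytr_f, kernel = "linear", scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    sgn <- if (strsplit(colnames(dv)[1], "/")[[1]][1] == pos) 1 else -1
    list(pred = as.character(pr), score = sgn * dv[, 1])
  } else {
    set.seed(seed)
    fit <- randomForest::randomForest(Xtr, ytr_f, ntree = n_trees)
    list(pred = as.character(stats::predict(fit, Xte)),
         score = stats::predict(fit, Xte, type = "prob")[, pos])
  }
}

#' Cross-validated evaluation of a ranked biomarker panel
#'
#' For every outer fold, gene selection and ranking run on the training split
#' only: an inner cross-validation (same LOOCV/K-fold rule) over the training
#' samples produces per-inner-fold selections, their union is ranked by the
#' requested method, and the top-`eta` genes form the fold's panel. A
#' classifier is then fitted on the training split restricted to the panel
#' and scored on the held-out test split; no information from any test split
#' reaches selection, ranking, or classifier fitting.
#'
#' Accuracy is averaged over folds. AUROC is computed from the pooled
#' test-split scores under LOOCV (single-sample folds have no ROC of their
#' own) and averaged over per-fold curves under K-fold.
#'
#' @param ds A complete [expression_dataset()] with binary labels.
#' @param method Ranking method: `"MGS_f"` (selection frequency) or
#'   `"MGS_rf"` (forest information gain).
#' @param classifier `"svm"` (linear kernel) or `"rf"` (random forest).
#' @param eta Panel size (default 10).
#' @param cfg An [mgs_config()].
#' @param seed Seed governing fold construction, the ranking forest and the
#'   random-forest classifier; results are reproducible given
#'   `(dataset, config, seed)`.
#' @param n_trees Trees for forest ranking and classifier (default 300).
#' @param k,loocv_threshold Outer fold scheme, see [make_folds()].
#' @param inner_k,inner_loocv_threshold Inner (selection) fold scheme;
#'   defaults mirror the outer scheme.
#' @return Object of class `mgs_evaluation`: accuracy, auroc, per-fold table,
#'   per-fold panels, scheme, positive class, config and seed. Folds where no
#'   gene could be selected are skipped with a warning and listed in
#'   `skipped_folds`.
#' @export
mgs_evaluate <- function(ds, method = c("MGS_f", "MGS_rf"),
                         classifier = c("svm", "rf"), eta = 10,
                         cfg = mgs_config(), seed = 1, n_trees = 300,
                         k = 10, loocv_threshold = 100,
                         inner_k = k, inner_loocv_threshold = loocv_threshold) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(unique(ds$labels)) != 2) stop("evaluation requires binary labels")
  if (anyNA(ds$expression)) stop("impute_missing() first")
  folds <- make_folds(ds$labels, seed = seed, k = k,
                      loocv_threshold = loocv_threshold)
  scheme <- attr(folds, "scheme")
  pos_code <- max(ds$labels)
  positive_class <- ds$label_names[pos_code + 1L]

  per_fold <- list(); panels <- list(); skipped <- integer(0)
  pooled_scores <- numeric(0); pooled_truth <- integer(0)
  fold_aurocs <- numeric(0)

  for (fi in seq_along(folds)) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_along(ds$labels), test_idx)
    tr <- subset_dataset(ds, samples = train_idx)

    inner <- make_folds(tr$labels, seed = seed + fi, k = inner_k,
                        loocv_threshold = inner_loocv_threshold)
    sels <- list()
    for (ii in seq_along(inner)) {
      itr <- subset_dataset(tr, samples = setdiff(seq_along(tr$labels),
                                                  inner[[ii]]))
      if (length(unique(itr$labels)) < 2) next
      s <- tryCatch(mgs_select(itr, cfg, fold_id = ii),
                    error = function(e) NULL)
      if (!is.null(s)) sels[[length(sels) + 1L]] <- s
    }
    if (length(sels) == 0) {
      warning("fold ", fi, ": no genes selected in any inner fold; skipped")
      skipped <- c(skipped, fi)
      next
    }
    u <- union_selections(sels)
    ranked <- if (method == "MGS_f") {
      rank_by_frequency(u)
    } else {
      ts <- stats::setNames(u$mean_score, u$gene_id)
      rank_by_forest(tr, genes = u$gene_id, n_trees = n_trees,
                     seed = seed + fi, tie_scores = ts)
    }
    panel <- top_eta(ranked, eta)
    panels[[fi]] <- panel

    gi <- match(panel, ds$gene_ids)
    Xtr <- t(ds$expression[gi, train_idx, drop = FALSE])
    Xte <- t(ds$expression[gi, test_idx, drop = FALSE])
    fp <- .fit_predict(Xtr, ds$labels[train_idx], Xte, classifier, n_trees,
                       seed + 1000 + fi)
    truth <- ds$labels[test_idx]
    acc <- mean(as.integer(fp$pred) == truth)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = fi, n_test = length(test_idx), accuracy = acc,
                 panel_size = length(panel))
    if (scheme == "LOOCV") {
      pooled_scores <- c(pooled_scores, fp$score)
      pooled_truth <- c(pooled_truth, truth)
    } else if (length(unique(truth)) == 2) {
      fold_aurocs <- c(fold_aurocs, auroc(fp$score, truth))
    }
  }
  if (length(per_fold) == 0) stop("no fold could be evaluated")
  per_fold <- do.call(rbind, per_fold)
  auc <- if (scheme == "LOOCV") auroc(pooled_scores, pooled_truth)
         else mean(fold_aurocs)
  structure(list(
    accuracy = mean(per_fold$accuracy), auroc = auc, per_fold = per_fold,
    panels = panels, method = method, classifier = classifier, eta = eta,
    scheme = if (scheme == "KFCV") sprintf("KFCV(%d)", k) else scheme,
    auroc_mode = if (scheme == "LOOCV") "pooled" else "per-fold mean",
    positive_class = positive_class, seed = seed, n_trees = n_trees,
    config = cfg, skipped_folds = skipped),
    class = "mgs_evaluation")
}

#' @export
print.mgs_evaluation <- function(x, ...) {
  cat(sprintf("mgs_evaluation: %s + %s, eta=%d, %s\n", x$method, x$classifier,
              x$eta, x$scheme))
  cat(sprintf("  accuracy: %.4f\n  AUROC (%s): %.4f\n", x$accuracy,
              x$auroc_mode, x$auroc))
  cat("  positive class:", x$positive_class, " seed:", x$seed, "\n")
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param x An `mgs_evaluation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(x, path) {
  stopifnot(inherits(x, "mgs_evaluation"))
  jsonlite::write_json(
    list(accuracy = x$accuracy, auroc = x$auroc, auroc_mode = x$auroc_mode,
         method = x$method, classifier = x$classifier, eta = x$eta,
         scheme = x$scheme, positive_class = x$positive_class, seed = x$seed,
         n_trees = x$n_trees, per_fold = x$per_fold,
         skipped_folds = x$skipped_folds, config = unclass(x$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
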