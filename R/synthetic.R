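## Synthetic benchmark generator: expression datasets with known ground truth
## emulating high-dimensional, low-sample disease studies — a handful of
## class-shifted informative genes, noisy redundant copies of them, gene
## pairs that are jointly but not marginally informative (XOR structure),
## and a large block of pure noise.

#' Specification of a synthetic benchmark dataset
#'
#' Defaults are a desk-scale caricature of a small disease-expression study:
#' 60 samples, balanced classes, 10 informative genes shifted by 1.5 SD
#' between classes, 2 noisy redundant copies of each informative gene,
#' 3 complementary (XOR) gene pairs and 2000 pure-noise genes.
#'
#' @param n_samples Number of samples (default 60).
#' @param class_balance Proportion of positive ("disease") samples
#'   (default 0.5).
#' @param n_informative Number of class-shifted informative genes
#'   (default 10).
#' @param effect_size Mean shift of informative genes between classes, in SD
#'   units (default 1.5).
#' @param n_redundant_per_informative Noisy copies per informative gene
#'   (default 2).
#' @param redundancy_noise SD of the additive noise on redundant copies
#'   (default 0.3).
#' @param n_complementary_pairs Number of XOR gene pairs: two coin genes whose
#'   exclusive-or equals the class, each marginally independent of it
#'   (default 3).
#' @param n_noise Number of pure-noise genes (default 2000).
#' @param xor_jitter SD of the Gaussian jitter added to the two-point XOR
#'   genes so they exercise the real discretizer (default 0.1).
#' @param seed RNG seed; generation is byte-identical given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60, class_balance = 0.5,
                           n_informative = 10, effect_size = 1.5,
                           n_redundant_per_informative = 2,
                           redundancy_noise = 0.3,
                           n_complementary_pairs = 3, n_noise = 2000,
                           xor_jitter = 0.1, seed = 1) {
  stopifnot(n_samples >= 2, class_balance > 0, class_balance < 1,
            n_informative >= 0, effect_size >= 0,
            n_redundant_per_informative >= 0, redundancy_noise >= 0,
            n_complementary_pairs >= 0, n_noise >= 0, xor_jitter >= 0)
  if (n_informative + n_complementary_pairs + n_noise == 0)
    stop("spec generates zero genes")
  structure(list(n_samples = as.integer(n_samples),
                 class_balance = class_balance,
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 n_redundant_per_informative =
                   as.integer(n_redundant_per_informative),
                 redundancy_noise = redundancy_noise,
                 n_complementary_pairs = as.integer(n_complementary_pairs),
                 n_noise = as.integer(n_noise), xor_jitter = xor_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Labels are Bernoulli(`class_balance`). Informative genes are
#' `N(0,1) + effect_size * label`; redundant genes are an informative parent
#' plus `N(0, redundancy_noise)` (informative *despite* being redundant —
#' the selection criterion must keep them); each complementary pair consists
#' of two jittered coin genes taking values near -1/+1 whose exclusive-or
#' encodes the class, so either gene alone is class-independent while the
#' pair is jointly deterministic; noise genes are `N(0,1)` independent of the
#' class.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with elements `dataset` (an
#'   [expression_dataset()], classes `control`/`disease`), `truth` (data.frame
#'   `gene_id`, `role` in informative/redundant/complementary/noise, and
#'   `partner`: the parent of a redundant copy or the other member of an XOR
#'   pair) and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  y <- stats::rbinom(n, 1, spec$class_balance)
  if (length(unique(y)) < 2)
    stop("degenerate draw: single-class labels; change seed or n_samples")

  blocks <- list(); ids <- character(0); roles <- character(0)
  partners <- character(0)

  if (spec$n_informative > 0) {
    inf <- matrix(stats::rnorm(spec$n_informative * n), spec$n_informative) +
      spec$effect_size * matrix(y, spec$n_informative, n, byrow = TRUE)
    blocks$inf <- inf
    inf_ids <- sprintf("inf%03d", seq_len(spec$n_informative))
    ids <- c(ids, inf_ids)
    roles <- c(roles, rep("informative", spec$n_informative))
    partners <- c(partners, rep(NA_character_, spec$n_informative))
    if (spec$n_redundant_per_informative > 0) {
      red <- do.call(rbind, lapply(seq_len(spec$n_informative), function(i) {
        k <- spec$n_redundant_per_informative
        matrix(rep(inf[i, ], k), k, byrow = TRUE) +
          matrix(stats::rnorm(k * n, 0, spec$redundancy_noise), k)
      }))
      blocks$red <- red
      for (i in seq_len(spec$n_informative)) {
        k <- spec$n_redundant_per_informative
        ids <- c(ids, sprintf("red%03d_%d", i, seq_len(k)))
        roles <- c(roles, rep("redundant", k))
        partners <- c(partners, rep(inf_ids[i], k))
      }
    }
  }
  if (spec$n_complementary_pairs > 0) {
    xr <- do.call(rbind, lapply(seq_len(spec$n_complementary_pairs),
                                function(i) {
      a <- stats::rbinom(n, 1, 0.5)
      b <- as.integer(xor(a, y))
      rbind(2 * a - 1 + stats::rnorm(n, 0, spec$xor_jitter),
            2 * b - 1 + stats::rnorm(n, 0, spec$xor_jitter))
    }))
    blocks$xor <- xr
    for (i in seq_len(spec$n_complementary_pairs)) {
      ids <- c(ids, sprintf("xorA%02d", i), sprintf("xorB%02d", i))
      roles <- c(roles, "complementary", "complementary")
      partners <- c(partners, sprintf("xorB%02d", i), sprintf("xorA%02d", i))
    }
  }
  if (spec$n_noise > 0) {
    blocks$noise <- matrix(stats::rnorm(spec$n_noise * n), spec$n_noise)
    ids <- c(ids, sprintf("noise%04d", seq_len(spec$n_noise)))
    roles <- c(roles, rep("noise", spec$n_noise))
    partners <- c(partners, rep(NA_character_, spec$n_noise))
  }
  X <- do.call(rbind, blocks)
  ds <- expression_dataset(X, gene_ids = ids,
                           sample_ids = sprintf("S%03d", seq_len(n)),
                           labels = y,
                           label_names = c("control", "disease"))
  truth <- data.frame(gene_id = ids, role = roles, partner = partners,
                      stringsAsFactors = FALSE)
  structure(list(dataset = ds, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset (seed ", x$spec$seed, ")\n", sep = "")
  print(x$dataset)
  print(table(x$truth$role))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression and labels CSVs in the dialect read by
#' [read_expression_csv()], plus the ground truth as JSON.
#'
#' @param x A `synthetic_dataset` from [generate_synthetic()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_csv(x$dataset, file.path(dir, "expression.csv"),
                       labels_path = file.path(dir, "labels.csv"))
  jsonlite::write_json(list(truth = x$truth, spec = unclass(x$spec)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
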