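## Greedy gene-subset selection: chi-squared screening of bias-corrected
## relevance at the minimal passing discretization level, then incremental
## admission by the complementary-information criterion with a +/- delta
## level sweep.

## Vectorized equal-width screening over all genes for a fixed level d.
## Returns corrected relevance, occupied levels and df per gene.
.screen_level_ew <- function(X, lo, rng, y, K, d) {
  N <- ncol(X)
  B <- floor((X - lo) / rng * d)
  B[B >= d] <- d - 1
  cnt <- array(0, c(nrow(X), d, K))
  for (k in seq_len(K)) {
    idx <- which(y == k - 1L)
    for (b in seq_len(d))
      cnt[, b, k] <- rowSums(B[, idx, drop = FALSE] == (b - 1))
  }
  tot_b <- rowSums(cnt, dims = 2)                     # gene x bin
  I <- rowSums(tot_b > 0)
  plog <- function(p) ifelse(p > 0, p * log2(p), 0)
  Hxy <- -rowSums(plog(matrix(cnt / N, nrow(X))))
  Hx <- -rowSums(plog(tot_b / N))
  Hy <- .entropy_counts(tabulate(y + 1L, K))
  mi <- Hx + Hy - Hxy
  df <- (I - 1) * (K - 1)
  list(j = mi - df / (2 * N * LN2), I = I, df = df)
}

#' Screen candidate genes by corrected relevance
#'
#' For each gene the discretization levels `d = 2..max_d` are swept in order
#' and the *first* level whose bias-corrected relevance [j_rel()] exceeds its
#' chi-squared critical value is recorded (minimal significant level); genes
#' never passing are excluded. Because every level is tested at `alpha`, the
#' per-gene false-candidate rate of the sweep exceeds `alpha` (a union over
#' correlated tests); each individual level test has size `alpha`.
#'
#' @param ds A complete (imputed) [expression_dataset()].
#' @param cfg An [mgs_config()].
#' @return Object of class `mgs_candidates`: a data.frame with columns
#'   `gene_index`, `gene_id`, `d` (minimal passing level), `n_levels`
#'   (occupied levels I at that d) and `score` (the corrected relevance),
#'   in original gene order. Zero rows when no gene passes.
#' @export
screen_candidates <- function(ds, cfg = mgs_config()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(cfg, "mgs_config"))
  X <- ds$expression
  if (anyNA(X)) stop("expression matrix has missing values; impute_missing() first")
  y <- ds$labels
  K <- length(unique(y))
  N <- ncol(X)
  G <- nrow(X)
  res_d <- integer(G); res_j <- numeric(G); res_I <- integer(G)
  if (cfg$scheme == "equal-width") {
    lo <- apply(X, 1, min)
    rng <- apply(X, 1, max) - lo
    rng[rng == 0] <- 1     # constant genes: all in bin 0, never significant
    pending <- seq_len(G)
    for (d in 2:cfg$max_d) {
      if (!length(pending)) break
      r <- .screen_level_ew(X[pending, , drop = FALSE], lo[pending],
                            rng[pending], y, K, d)
      pass <- r$df >= 1 & r$j > chi2_critical_mi(pmax(r$df, 1), cfg$alpha, N,
                                                 cfg$critical_scale)
      if (any(pass)) {
        g <- pending[pass]
        res_d[g] <- d; res_j[g] <- r$j[pass]; res_I[g] <- r$I[pass]
        pending <- pending[!pass]
      }
    }
  } else {
    for (g in seq_len(G)) {
      for (d in 2:cfg$max_d) {
        jr <- j_rel(X[g, ], y, d, cfg$scheme)
        df <- attr(jr, "df")
        if (df >= 1 &&
            jr > chi2_critical_mi(df, cfg$alpha, N, cfg$critical_scale)) {
          res_d[g] <- d; res_j[g] <- as.numeric(jr)
          res_I[g] <- attr(jr, "n_levels")
          break
        }
      }
    }
  }
  keep <- which(res_d > 0)
  out <- data.frame(gene_index = keep, gene_id = ds$gene_ids[keep],
                    d = res_d[keep], n_levels = res_I[keep],
                    score = res_j[keep], stringsAsFactors = FALSE)
  class(out) <- c("mgs_candidates", "data.frame")
  out
}

#' Select a gene subset by the complementary-information criterion
#'
#' Candidates are sorted by decreasing corrected relevance (ties broken by
#' original gene order, stable) and the top candidate seeds the selected set.
#' Each remaining candidate is re-discretized at every level in
#' `d_i - delta .. d_i + delta` (clamped to `[2, max_d]`) and admitted iff the
#' criterion [j_mgs()] exceeds its chi-squared critical value at composite
#' degrees of freedom for at least one level in the sweep; the passing level
#' with maximal criterion value is stored. With
#' `cfg$literal_algorithm1 = TRUE` the loop instead keeps the *last* passing
#' level and admits any candidate whose running score is positive even when no
#' level passed (the literal transcription; see the methods vignette).
#'
#' @param candidates An `mgs_candidates` data.frame from [screen_candidates()].
#' @param ds The same complete [expression_dataset()].
#' @param cfg An [mgs_config()].
#' @param fold_id Optional integer recorded in the result (cross-validation
#'   bookkeeping).
#' @return Object of class `mgs_selection`: list with `selected` (data.frame
#'   `gene_index`, `gene_id`, `d`, `n_levels`, `score`, in selection order),
#'   `fold_id`, `n_candidates` and `config`.
#' @export
select_subset <- function(candidates, ds, cfg = mgs_config(), fold_id = NA_integer_) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(cfg, "mgs_config"))
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("no significant genes: candidate set is empty")
  X <- ds$expression
  y <- .code_discrete(ds$labels)
  K <- y$n
  N <- ncol(X)
  ord <- order(-candidates$score, candidates$gene_index)
  cand <- candidates[ord, , drop = FALSE]

  sel_idx <- cand$gene_index[1]
  sel_d <- cand$d[1]
  sel_score <- cand$score[1]
  partners <- list(discretize(X[sel_idx, ], sel_d, cfg$scheme))

  for (ci in seq_len(nrow(cand))[-1]) {
    gi <- cand$gene_index[ci]
    x <- X[gi, ]
    lev <- max(2L, cand$d[ci] - cfg$delta):min(cfg$max_d, cand$d[ci] + cfg$delta)
    best_j <- -Inf; best_d <- NA_integer_; passed <- FALSE
    lit_j <- cand$score[ci]; lit_d <- cand$d[ci]; lit_T <- 0  # literal mode state
    for (d in lev) {
      dg <- discretize(x, d, cfg$scheme)
      if (dg$n_levels < 2) next
      r <- .j_mgs_full(dg$bins, dg$d, dg$n_levels, y$bins, K, partners, N)
      if (r$df <= 0) next
      crit <- chi2_critical_mi(r$df, cfg$alpha, N, cfg$critical_scale)
      if (r$j > crit) {
        passed <- TRUE
        lit_d <- d; lit_T <- crit; lit_j <- r$j
        if (r$j > best_j) { best_j <- r$j; best_d <- d }
      }
    }
    take <- if (cfg$literal_algorithm1) lit_j > lit_T else passed
    if (take) {
      d_star <- if (cfg$literal_algorithm1) lit_d else best_d
      j_star <- if (cfg$literal_algorithm1) lit_j else best_j
      dg <- discretize(x, d_star, cfg$scheme)
      sel_idx <- c(sel_idx, gi)
      sel_d <- c(sel_d, d_star)
      sel_score <- c(sel_score, j_star)
      partners[[length(partners) + 1L]] <- dg
    }
  }
  selected <- data.frame(
    gene_index = sel_idx, gene_id = ds$gene_ids[sel_idx], d = sel_d,
    n_levels = vapply(partners, function(p) p$n_levels, 0L),
    score = sel_score, stringsAsFactors = FALSE)
  structure(list(selected = selected, fold_id = fold_id,
                 n_candidates = nrow(candidates), config = cfg),
            class = "mgs_selection")
}

#' @export
print.mgs_selection <- function(x, ...) {
  cat("mgs_selection:", nrow(x$selected), "genes selected from",
      x$n_candidates, "candidates\n")
  if (!is.na(x$fold_id)) cat("fold:", x$fold_id, "\n")
  print(utils::head(x$selected, 10))
  if (nrow(x$selected) > 10) cat("...\n")
  invisible(x)
}

#' Screen and select in one call
#'
#' @inheritParams select_subset
#' @param ds A complete [expression_dataset()].
#' @return An `mgs_selection`; errors with "no significant genes" when
#'   screening admits no candidate.
#' @export
mgs_select <- function(ds, cfg = mgs_config(), fold_id = NA_integer_) {
  select_subset(screen_candidates(ds, cfg), ds, cfg, fold_id)
}

#' Serialize a selection to JSON
#'
#' @param x An `mgs_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "mgs_selection"))
  jsonlite::write_json(
    list(selected = x$selected, fold_id = x$fold_id,
         n_candidates = x$n_candidates, config = unclass(x$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
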