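## Information-theoretic core: discretization, entropy, (conditional) mutual
## information in bits, finite-sample bias corrections, chi-squared thresholds.
## All probabilities are empirical; 0 * log 0 is taken as 0 throughout.

LN2 <- log(2)

## entropy in bits from a vector of counts (zeros allowed)
.entropy_counts <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log2(p))
}

## MI in bits from 0-based bin vectors with nominal level counts nx, ny
.mi_bins <- function(bx, by, nx, ny) {
  j <- tabulate(bx * ny + by + 1L, nx * ny)
  .entropy_counts(tabulate(bx + 1L, nx)) +
    .entropy_counts(tabulate(by + 1L, ny)) - .entropy_counts(j)
}

## CMI I(X;Y|Z) in bits: H(XZ) + H(YZ) - H(XYZ) - H(Z)
.cmi_bins <- function(bx, by, bz, nx, ny, nz) {
  .entropy_counts(tabulate(bx * nz + bz + 1L, nx * nz)) +
    .entropy_counts(tabulate(by * nz + bz + 1L, ny * nz)) -
    .entropy_counts(tabulate((bx * ny + by) * nz + bz + 1L, nx * ny * nz)) -
    .entropy_counts(tabulate(bz + 1L, nz))
}

## coerce any discrete vector to 0-based integer codes plus level count
.code_discrete <- function(v) {
  if (inherits(v, "discretized_gene"))
    return(list(bins = v$bins, n = v$d, occupied = v$n_levels))
  f <- as.integer(factor(v))
  list(bins = f - 1L, n = max(f), occupied = length(unique(f)))
}

#' Selection configuration
#'
#' Bundles the tunable parameters of screening and selection.
#'
#' @param alpha Significance level of the chi-squared tests (default 0.05).
#' @param max_d Maximum discretization level swept during screening
#'   (default 10).
#' @param delta Half-width of the discretization sweep around a candidate's
#'   screening level during selection (non-negative integer, default 2).
#' @param scheme Discretization scheme: `"equal-width"` (default) or
#'   `"equal-frequency"`.
#' @param critical_scale How the chi-squared critical value is placed on the
#'   bias-corrected bit scale: `"corrected"` (default; the null mean
#'   `df/(2N ln 2)` is subtracted, making the comparison identical to the raw
#'   chi-squared test) or `"literal"` (the quantile is only rescaled).
#' @param literal_algorithm1 Reproduce the literal transcription of the greedy
#'   selection loop (keep the *last* passing level; admit any candidate whose
#'   running score is positive even if no sweep level passed). Default `FALSE`:
#'   strict mode requires the test to pass and keeps the best passing level.
#' @return An object of class `mgs_config`.
#' @export
mgs_config <- function(alpha = 0.05, max_d = 10, delta = 2,
                       scheme = c("equal-width", "equal-frequency"),
                       critical_scale = c("corrected", "literal"),
                       literal_algorithm1 = FALSE) {
  scheme <- match.arg(scheme)
  critical_scale <- match.arg(critical_scale)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            max_d >= 2, delta >= 0)
  structure(list(alpha = alpha, max_d = as.integer(max_d),
                 delta = as.integer(delta), scheme = scheme,
                 critical_scale = critical_scale,
                 literal_algorithm1 = isTRUE(literal_algorithm1)),
            class = "mgs_config")
}

#' Discretize a continuous expression vector
#'
#' Maps values to integer bins `0..d-1`. The default scheme uses `d`
#' equal-width bins over the observed `[min, max]`; the maximum value is
#' assigned to the top bin. A constant vector maps every sample to bin 0
#' (one occupied level). The equal-frequency alternative places bin edges at
#' empirical quantiles.
#'
#' @param values Numeric vector with at least one finite value and no `NA`
#'   (impute first, see [impute_missing()]).
#' @param d Number of bins, `>= 2`.
#' @param scheme `"equal-width"` (default) or `"equal-frequency"`.
#' @return An object of class `discretized_gene`: list with `bins` (0-based
#'   integer per sample), `d`, `edges` (`d+1` boundaries) and `n_levels`
#'   (number of *occupied* bins, the `I` of the bias formulas).
#' @examples
#' discretize(c(0, 1, 2, 3), 2)$bins   # 0 0 1 1
#' @export
discretize <- function(values, d, scheme = c("equal-width", "equal-frequency")) {
  scheme <- match.arg(scheme)
  if (length(values) == 0) stop("empty vector")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing; impute first")
  if (!is.numeric(d) || length(d) != 1 || d < 2) stop("d must be >= 2")
  d <- as.integer(d)
  r <- range(values)
  if (r[1] == r[2]) {
    bins <- integer(length(values))
    edges <- r[1] + seq(0, 1, length.out = d + 1)
  } else if (scheme == "equal-width") {
    edges <- seq(r[1], r[2], length.out = d + 1)
    bins <- as.integer(floor((values - r[1]) / (r[2] - r[1]) * d))
    bins[bins >= d] <- d - 1L
  } else {
    q <- stats::quantile(values, probs = seq(0, 1, length.out = d + 1),
                         names = FALSE)
    inner <- q[-c(1, d + 1)]
    bins <- as.integer(findInterval(values, sort(unique(inner)),
                                    left.open = FALSE))
    edges <- q
    if (any(duplicated(edges))) edges <- edges + seq(0, 1e-9, length.out = d + 1)
  }
  structure(list(bins = bins, d = d, edges = edges,
                 n_levels = length(unique(bins))),
            class = "discretized_gene")
}

#' Mutual information in bits
#'
#' Empirical `I(X;Y)` from the joint histogram of two discrete vectors,
#' non-negative and bounded by `min(H(X), H(Y))`.
#'
#' @param x A [discretize()]d gene or any discrete vector.
#' @param y A discrete vector (e.g. class labels) of the same length.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  cx <- .code_discrete(x); cy <- .code_discrete(y)
  if (length(cx$bins) != length(cy$bins)) stop("length mismatch")
  .mi_bins(cx$bins, cy$bins, cx$n, cy$n)
}

#' Conditional mutual information in bits
#'
#' Empirical `I(X;Y|Z) = sum_z p(z) I(X;Y|Z=z)`, non-negative.
#'
#' @param x,y [discretize()]d genes or discrete vectors.
#' @param z Conditioning discrete vector (e.g. class labels).
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, y, z) {
  cx <- .code_discrete(x); cy <- .code_discrete(y); cz <- .code_discrete(z)
  if (length(cx$bins) != length(cy$bins) || length(cx$bins) != length(cz$bins))
    stop("length mismatch")
  .cmi_bins(cx$bins, cy$bins, cz$bins, cx$n, cy$n, cz$n)
}

#' Finite-sample bias of the relevance estimate
#'
#' Under independence, `2 N ln2 * I(X;C)` is asymptotically chi-squared with
#' `(I-1)(K-1)` degrees of freedom, so the empirical MI has null mean
#' `(I-1)(K-1) / (2 N ln 2)` bits — the correction subtracted from relevance.
#'
#' @param I_levels Occupied discretization levels of the gene.
#' @param K_classes Number of classes.
#' @param N Number of samples.
#' @return Bias in bits.
#' @export
relevance_bias <- function(I_levels, K_classes, N) {
  stopifnot(I_levels >= 1, K_classes >= 1, N >= 1)
  (I_levels - 1) * (K_classes - 1) / (2 * N * LN2)
}

#' Finite-sample bias of the complementary-information estimate
#'
#' Null mean of the empirical conditional MI `I(X;Y|C)`:
#' `(I-1)(J-1) K / (2 N ln 2)` bits.
#'
#' @param I_levels,J_levels Occupied levels of the candidate and the selected
#'   partner gene.
#' @param K_classes Number of classes.
#' @param N Number of samples.
#' @return Bias in bits.
#' @export
complementary_bias <- function(I_levels, J_levels, K_classes, N) {
  stopifnot(I_levels >= 1, J_levels >= 1, K_classes >= 1, N >= 1)
  (I_levels - 1) * (J_levels - 1) * K_classes / (2 * N * LN2)
}

#' Chi-squared critical value on the bias-corrected bit scale
#'
#' Critical value against which the bias-corrected statistics are compared.
#' On the default `"corrected"` scale the null mean `df/(2N ln 2)` is
#' subtracted from the rescaled quantile, so that
#' `j > chi2_critical_mi(df, ...)` is algebraically identical to the raw-scale
#' test `2 N ln2 * MI > qchisq(1 - alpha, df)`. The `"literal"` scale omits
#' the subtraction. Monotone increasing in `df`, decreasing in `N`.
#'
#' @param df Degrees of freedom (positive; non-integer allowed for composite
#'   statistics).
#' @param alpha Significance level.
#' @param N Number of samples.
#' @param scale `"corrected"` (default) or `"literal"`.
#' @return Critical value in bits.
#' @export
chi2_critical_mi <- function(df, alpha = 0.05, N, scale = c("corrected", "literal")) {
  scale <- match.arg(scale)
  if (any(df <= 0)) stop("df must be positive")
  q <- stats::qchisq(1 - alpha, df)
  (q - if (scale == "corrected") df else 0) / (2 * N * LN2)
}

#' Bias-corrected relevance of a gene
#'
#' Discretizes the gene at level `d` and returns
#' `I(g^d; C) - (I-1)(K-1)/(2N ln 2)`, with `I` the number of occupied bins
#' and `K` the number of observed classes.
#'
#' @param gene Numeric expression vector.
#' @param labels Discrete class labels, same length.
#' @param d Discretization level (`>= 2`).
#' @param scheme Discretization scheme, see [discretize()].
#' @return Corrected relevance in bits, with attributes `n_levels` (I) and
#'   `df` = `(I-1)(K-1)`.
#' @export
j_rel <- function(gene, labels, d, scheme = "equal-width") {
  if (length(gene) != length(labels)) stop("length mismatch")
  dg <- discretize(gene, d, scheme)
  cy <- .code_discrete(labels)
  N <- length(gene)
  K <- cy$occupied
  mi <- .mi_bins(dg$bins, cy$bins, dg$d, cy$n)
  out <- mi - relevance_bias(dg$n_levels, K, N)
  attr(out, "n_levels") <- dg$n_levels
  attr(out, "df") <- (dg$n_levels - 1) * (K - 1)
  out
}

## full selection criterion with its composite df; `selected` is a non-empty
## list of discretized_gene partners
.j_mgs_full <- function(bins, n_nominal, I, labels_code, K, selected, N) {
  rel <- .mi_bins(bins, labels_code, n_nominal, K) -
    relevance_bias(I, K, N)
  m <- length(selected)
  comp <- numeric(m)
  dfc <- numeric(m)
  for (s in seq_len(m)) {
    p <- selected[[s]]
    comp[s] <- .cmi_bins(bins, p$bins, labels_code, n_nominal, p$d, K) -
      complementary_bias(I, p$n_levels, K, N)
    dfc[s] <- (I - 1) * (p$n_levels - 1) * K
  }
  list(j = rel + mean(comp),
       df = (I - 1) * (K - 1) + mean(dfc))
}

#' Selection criterion: corrected relevance plus mean complementary information
#'
#' For a candidate gene `g_i` discretized at level `d` and a non-empty
#' selected set `G_S`, returns
#' `J(g_i) = I(g_i;C) - (I-1)(K-1)/(2N ln2) +
#'   mean_{g_s in G_S} [ I(g_i; g_s | C) - (I-1)(J_s-1)K/(2N ln2) ]`.
#' Redundancy between genes is deliberately *not* penalized: a gene correlated
#' with an already-selected one is kept whenever it carries additional
#' class-conditional information.
#'
#' @param gene Numeric expression vector of the candidate.
#' @param labels Discrete class labels.
#' @param d Discretization level for the candidate.
#' @param selected Non-empty list of [discretize()]d partner genes (each at its
#'   stored level; `J_s` is the partner's occupied level count).
#' @param scheme Discretization scheme.
#' @return Criterion value in bits, with attribute `df`: the composite degrees
#'   of freedom `(I-1)(K-1) + mean_s (I-1)(J_s-1)K` used for its test.
#' @export
j_mgs <- function(gene, labels, d, selected, scheme = "equal-width") {
  if (!is.list(selected) || length(selected) == 0)
    stop("selected set must be non-empty; use j_rel() for the first gene")
  if (!all(vapply(selected, inherits, TRUE, "discretized_gene")))
    stop("selected must be a list of discretized genes")
  if (length(gene) != length(labels)) stop("length mismatch")
  dg <- discretize(gene, d, scheme)
  cy <- .code_discrete(labels)
  res <- .j_mgs_full(dg$bins, dg$d, dg$n_levels, cy$bins, cy$n, selected,
                     length(gene))
  out <- res$j
  attr(out, "df") <- res$df
  out
}
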