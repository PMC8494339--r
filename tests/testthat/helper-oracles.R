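# Independent brute-force oracles. These loop over outcome combinations or
# sample pairs directly and share no code with the package internals.

oracle_mi <- function(x, y) {
  n <- length(x)
  s <- 0
  for (a in unique(x)) for (b in unique(y)) {
    p <- sum(x == a & y == b) / n
    if (p > 0) s <- s + p * log2(p / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  s
}

oracle_cmi <- function(x, y, z) {
  n <- length(z)
  s <- 0
  for (c in unique(z)) {
    i <- z == c
    s <- s + (sum(i) / n) * oracle_mi(x[i], y[i])
  }
  s
}

oracle_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log2(p))
}

oracle_wig <- function(parent, left, right, n_total) {
  nt <- length(parent)
  hl <- if (length(left)) oracle_entropy(left) else 0
  hr <- if (length(right)) oracle_entropy(right) else 0
  (nt / n_total) * (oracle_entropy(parent) -
                    (length(left) / nt) * hl - (length(right) / nt) * hr)
}

## pair counting over all positive x negative pairs; ties score 1/2
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == max(labels))
  neg <- which(labels != max(labels))
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}
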