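# Fixtures are built in code at test time; nothing is stored on disk.

## small dataset with n_signal genes that separate the classes perfectly
## (large shift, tiny within-class noise) plus pure-noise genes
make_separable_ds <- function(n = 20, n_signal = 5, n_noise = 8, gap = 3,
                              seed = 7) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  sig <- matrix(rep(y * gap, n_signal), n_signal, byrow = TRUE) +
    matrix(rnorm(n_signal * n, 0, 0.1), n_signal)
  ns <- matrix(rnorm(n_noise * n), n_noise)
  expression_dataset(rbind(sig, ns),
                     gene_ids = c(sprintf("sep%d", seq_len(n_signal)),
                                  sprintf("ns%d", seq_len(n_noise))),
                     sample_ids = sprintf("S%02d", seq_len(n)),
                     labels = y, label_names = c("control", "disease"))
}

## the worked-example fold selections
toy_fold_selections <- function() {
  list(c("g1", "g3", "g4", "g5", "g6"),
       c("g1", "g2", "g4", "g6"))
}

## printed per-gene ranking scores of the illustrative 20-gene example
toy_score_table <- function() {
  data.frame(
    gene_id = c("g2", "g3", "g5", "g9", "g12", "g13", "g15", "g17", "g19", "g20"),
    f_score = c(0.8, 0.8, 0.7, 0.6, 0.6, 0.5, 0.4, 0.4, 0.2, 0.2),
    rf_score = c(0.92, 0.97, 0.73, 0.76, 0.69, 0.89, 0.44, 0.57, 0.39, 0.21),
    stringsAsFactors = FALSE)
}

## write a small genes-as-rows expression CSV + labels CSV; returns the paths
write_toy_csv <- function(dir = tempfile("toycsv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expr.csv")
  lab_path <- file.path(dir, "labels.csv")
  writeLines(c("probe_id,gene_symbol,S1,S2,S3,S4",
               "p1,A,1,3,2,4",
               "p2,A,3,5,4,6",
               "p3,B,0.5,,1.5,2",
               "p4,C,7,8,9,10"), expr_path)
  writeLines(c("sample_id,class",
               "S1,control", "S2,control", "S3,disease", "S4,disease"),
             lab_path)
  list(expression = expr_path, labels = lab_path)
}
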