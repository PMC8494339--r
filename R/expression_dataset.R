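#' Construct an expression dataset
#'
#' Container for a genes-by-samples expression matrix with per-sample class
#' labels. Gene identifiers may be duplicated before probe collapsing; use
#' [collapse_probes()] to merge rows sharing a gene symbol.
#'
#' @param expression Numeric matrix, genes in rows and samples in columns.
#'   Missing measurements are `NA`, never zero.
#' @param gene_ids Character vector of gene symbols, one per row. Defaults to
#'   `rownames(expression)`.
#' @param sample_ids Character vector of sample identifiers, one per column.
#'   Defaults to `colnames(expression)`.
#' @param labels Per-sample class labels: integer codes in `0..K-1`, or a
#'   character/factor vector which is coded by sorted class-name order
#'   (deterministic).
#' @param probe_ids Optional probe identifiers. Before collapsing: a character
#'   vector, one probe per row. After collapsing: a list of character vectors
#'   recording which probes were merged into each gene.
#' @param label_names Optional class names for integer `labels`; ignored when
#'   `labels` is character/factor.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `expression`, `gene_ids`, `probe_ids`, `sample_ids`, `labels` (integer
#'   codes) and `label_names`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(x, labels = c("control", "control", "disease", "disease"))
#' ds$labels       # 0 0 1 1
#' @export
expression_dataset <- function(expression, gene_ids = rownames(expression),
                               sample_ids = colnames(expression), labels,
                               probe_ids = NULL, label_names = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required (or set rownames)")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(expression)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(expression))
    stop("length(gene_ids) must equal nrow(expression)")
  if (length(sample_ids) != ncol(expression))
    stop("length(sample_ids) must equal ncol(expression)")
  if (length(labels) != ncol(expression))
    stop("labels length (", length(labels), ") must equal number of samples (",
         ncol(expression), ")")
  if (is.character(labels) || is.factor(labels)) {
    label_names <- sort(unique(as.character(labels)))
    labels <- match(as.character(labels), label_names) - 1L
  } else {
    labels <- as.integer(labels)
    if (any(is.na(labels)) || any(labels < 0))
      stop("integer labels must be non-negative codes 0..K-1")
    if (is.null(label_names)) label_names <- as.character(sort(unique(labels)))
  }
  if (length(unique(labels)) < 2)
    stop("at least 2 distinct label values are required")
  if (!is.null(probe_ids) && !is.list(probe_ids)) {
    probe_ids <- as.character(probe_ids)
    if (length(probe_ids) != nrow(expression))
      stop("length(probe_ids) must equal nrow(expression)")
  }
  dimnames(expression) <- list(gene_ids, sample_ids)
  structure(list(expression = expression, gene_ids = gene_ids,
                 probe_ids = probe_ids, sample_ids = sample_ids,
                 labels = labels, label_names = label_names),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  tab <- table(x$label_names[x$labels + 1L])
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  n_na <- sum(is.na(x$expression))
  if (n_na > 0) cat("missing cells:", n_na, "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$expression)

#' Subset an expression dataset by samples and/or genes
#'
#' @param ds An [expression_dataset()].
#' @param samples Integer/logical index or character sample ids; `NULL` keeps all.
#' @param genes Integer/logical index or character gene ids; `NULL` keeps all.
#' @return An `expression_dataset` with the requested rows/columns, labels
#'   kept aligned to the retained samples.
#' @export
subset_dataset <- function(ds, samples = NULL, genes = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  si <- if (is.null(samples)) seq_along(ds$sample_ids) else {
    if (is.character(samples)) match(samples, ds$sample_ids) else
      seq_along(ds$sample_ids)[samples]
  }
  gi <- if (is.null(genes)) seq_along(ds$gene_ids) else {
    if (is.character(genes)) match(genes, ds$gene_ids) else
      seq_along(ds$gene_ids)[genes]
  }
  if (anyNA(si)) stop("unknown sample id")
  if (anyNA(gi)) stop("unknown gene id")
  expression_dataset(ds$expression[gi, si, drop = FALSE],
                     gene_ids = ds$gene_ids[gi], sample_ids = ds$sample_ids[si],
                     labels = ds$labels[si],
                     probe_ids = if (is.list(ds$probe_ids)) ds$probe_ids[gi]
                                 else ds$probe_ids[gi],
                     label_names = ds$label_names)
}

#' Read an expression matrix and labels from CSV
#'
#' Expected layout for `orientation = "genes-as-rows"` (the canonical dialect):
#' comma-separated UTF-8 with a header row; first column the probe id, second
#' column the gene symbol, remaining columns one per sample. For
#' `orientation = "samples-as-rows"` the file is the transpose: first column
#' the sample id, remaining columns one gene each, headed `probe|symbol` (or a
#' bare symbol, in which case the probe id equals the symbol). Blank cells
#' are recorded as missing (`NA`), never as zero.
#'
#' @param path Path to the expression CSV.
#' @param labels Either a path to a labels CSV with columns
#'   `(sample_id, class)`, or a vector of per-sample labels in file sample
#'   order. Class strings are mapped to codes `0..K-1` by sorted order.
#' @param orientation `"genes-as-rows"` (default) or `"samples-as-rows"`.
#' @return An [expression_dataset()] *before* probe collapsing.
#' @seealso [collapse_probes()], [drop_empty_genes()], [write_expression_csv()]
#' @export
read_expression_csv <- function(path,
                                labels,
                                orientation = c("genes-as-rows",
                                                "samples-as-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e)))
  if (orientation == "samples-as-rows") {
    if (ncol(raw) < 2) stop("malformed CSV: expected sample_id plus gene columns")
    sample_ids <- raw[[1]]
    heads <- colnames(raw)[-1]
    sp <- strsplit(heads, "|", fixed = TRUE)
    probe_ids <- vapply(sp, `[[`, "", 1)
    gene_ids <- vapply(sp, function(v) v[[length(v)]], "")
    vals <- t(as.matrix(raw[, -1, drop = FALSE]))
  } else {
    if (ncol(raw) < 3) stop("malformed CSV: expected probe, symbol and sample columns")
    probe_ids <- raw[[1]]
    gene_ids <- raw[[2]]
    sample_ids <- colnames(raw)[-(1:2)]
    vals <- as.matrix(raw[, -(1:2), drop = FALSE])
  }
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s': \"%s\"",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  if (missing(labels) || is.null(labels))
    stop("labels are required: supply a labels CSV path or a vector")
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    lab <- read_labels_csv(labels)
    m <- match(sample_ids, lab$sample_id)
    if (anyNA(m))
      stop("labels file is missing samples: ",
           paste(sample_ids[is.na(m)], collapse = ", "))
    labels <- lab$class[m]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels length does not match the number of samples")
  }
  expression_dataset(num, gene_ids = gene_ids, sample_ids = sample_ids,
                     labels = labels, probe_ids = probe_ids)
}

#' Read a sample-to-class labels CSV
#'
#' @param path CSV with columns `sample_id` and `class`.
#' @return A data.frame with character columns `sample_id` and `class`.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  lab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "class") %in% colnames(lab)))
    stop("labels CSV must have columns 'sample_id' and 'class'")
  lab[, c("sample_id", "class")]
}

#' Write an expression dataset (and labels) to CSV
#'
#' Writes the canonical genes-as-rows dialect read by [read_expression_csv()].
#' Missing entries are written as empty cells. When the dataset carries
#' preprocessing provenance (from [collapse_probes()] / [drop_empty_genes()]),
#' a JSON sidecar listing merged probes and dropped genes can be emitted.
#'
#' @param ds An [expression_dataset()].
#' @param path Output CSV path.
#' @param labels_path Optional path for the `(sample_id, class)` labels CSV.
#' @param provenance_path Optional path for the JSON provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(ds, path, labels_path = NULL,
                                 provenance_path = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  probes <- if (is.null(ds$probe_ids)) ds$gene_ids
            else if (is.list(ds$probe_ids))
              vapply(ds$probe_ids, paste, "", collapse = ";")
            else ds$probe_ids
  out <- data.frame(probe_id = probes, gene_symbol = ds$gene_ids,
                    ds$expression, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[-(1:2)] <- ds$sample_ids
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(labels_path)) {
    utils::write.csv(data.frame(sample_id = ds$sample_ids,
                                class = ds$label_names[ds$labels + 1L]),
                     labels_path, row.names = FALSE)
  }
  if (!is.null(provenance_path)) {
    prov <- list(
      merged_probes = attr(ds, "merged_probes"),
      dropped_genes = attr(ds, "dropped_genes"),
      n_genes = nrow(ds$expression), n_samples = ncol(ds$expression))
    jsonlite::write_json(prov, provenance_path, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Collapse probes mapping to the same gene symbol
#'
#' Rows sharing a gene symbol (same symbol, different probe id) are merged
#' into a single row by the unweighted arithmetic mean, computed per sample
#' over the non-missing probe measurements. Symbols keep their order of first
#' appearance; with no duplicated symbols the dataset is returned unchanged
#' apart from probe provenance.
#'
#' @param ds An [expression_dataset()].
#' @return An `expression_dataset` with unique `gene_ids`; `probe_ids` becomes
#'   a list recording which probes were merged into each row, and the
#'   `merged_probes` attribute summarises symbols that were actually merged.
#' @export
collapse_probes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  probes <- if (is.null(ds$probe_ids)) ds$gene_ids else ds$probe_ids
  if (is.list(probes)) probes <- vapply(probes, paste, "", collapse = ";")
  syms <- unique(ds$gene_ids)
  groups <- split(seq_along(ds$gene_ids), factor(ds$gene_ids, levels = syms))
  expr <- matrix(NA_real_, length(syms), ncol(ds$expression))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    if (length(rows) == 1L) {
      expr[i, ] <- ds$expression[rows, ]
    } else {
      m <- colMeans(ds$expression[rows, , drop = FALSE], na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      expr[i, ] <- m
    }
  }
  probe_list <- lapply(groups, function(rows) probes[rows])
  merged <- probe_list[vapply(groups, length, 0L) > 1L]
  out <- expression_dataset(expr, gene_ids = syms, sample_ids = ds$sample_ids,
                            labels = ds$labels, probe_ids = unname(probe_list),
                            label_names = ds$label_names)
  attr(out, "merged_probes") <- merged
  attr(out, "dropped_genes") <- attr(ds, "dropped_genes")
  out
}

#' Drop genes with no expression values
#'
#' Removes rows whose every entry is missing. Rows with at least one observed
#' value are retained, partial missingness included.
#'
#' @param ds An [expression_dataset()], normally after [collapse_probes()].
#' @return An `expression_dataset` without all-missing rows; the ids of the
#'   removed genes are recorded in the `dropped_genes` attribute.
#' @export
drop_empty_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  keep <- rowSums(!is.na(ds$expression)) > 0
  if (!any(keep)) stop("no usable genes: every gene is entirely missing")
  dropped <- ds$gene_ids[!keep]
  out <- subset_dataset(ds, genes = which(keep))
  attr(out, "merged_probes") <- attr(ds, "merged_probes")
  attr(out, "dropped_genes") <- c(attr(ds, "dropped_genes"), dropped)
  out
}

#' Impute remaining missing values by per-gene median
#'
#' Genes with partial missingness are filled with the median of their observed
#' values — a robust, deterministic choice. Selection requires a complete
#' matrix, so this runs by default at the head of the pipeline; disable via
#' the `impute` argument of [preprocess_dataset()] if values are known
#' complete.
#'
#' @param ds An [expression_dataset()] with no all-missing rows.
#' @return A complete `expression_dataset`.
#' @export
impute_missing <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  expr <- ds$expression
  miss <- which(rowSums(is.na(expr)) > 0)
  for (i in miss) {
    v <- expr[i, ]
    if (all(is.na(v))) stop("gene '", ds$gene_ids[i],
                            "' is entirely missing; drop_empty_genes() first")
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    expr[i, ] <- v
  }
  ds$expression <- expr
  ds
}

#' Standard preprocessing: collapse probes, drop empty genes, impute
#'
#' @param ds An [expression_dataset()] as read by [read_expression_csv()].
#' @param impute Fill remaining missing values by per-gene median
#'   (default `TRUE`).
#' @return A preprocessed `expression_dataset` carrying provenance attributes.
#' @export
preprocess_dataset <- function(ds, impute = TRUE) {
  out <- drop_empty_genes(collapse_probes(ds))
  if (impute) out <- impute_missing(out)
  out
}
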