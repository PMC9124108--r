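#' Construct an expression set
#'
#' The package's in-memory container for a labelled expression matrix:
#' samples in rows, genes in columns, one binary class label per sample.
#' Microarray matrices are routinely genes-by-samples on disk; the reader
#' ([read_expression()]) transposes to this canonical orientation.
#'
#' @param values numeric matrix, `n_samples x n_genes`, no missing values.
#' @param labels per-sample class labels in `{0, 1}` (integer or coercible).
#' @param gene_ids character vector of gene identifiers; defaults to the
#'   column names of `values` or `gene_1 ... gene_p`.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   row names or `sample_1 ... sample_n`.
#' @return An object of class `"expression_set"`: a list with elements
#'   `values`, `labels`, `gene_ids`, `sample_ids`.
#' @export
#' @examples
#' es <- expression_set(matrix(rnorm(12), 4, 3), c(0, 0, 1, 1))
#' dim(es)
expression_set <- function(values, labels, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L || nrow(values) == 0L || ncol(values) == 0L)
    stop_invalid("expression matrix is empty")
  if (!is.numeric(values))
    stop_invalid("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop_invalid("expression matrix contains missing or non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop_invalid("length(labels) must equal nrow(values)")
  if (!all(labels %in% c(0L, 1L)))
    stop_invalid("labels must lie in {0, 1}")
  if (length(unique(labels)) < 2L && nrow(values) > 1L)
    warning("only one class present in labels")
  if (is.null(gene_ids))
    gene_ids <- colnames(values) %||% paste0("gene_", seq_len(ncol(values)))
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("sample_", seq_len(nrow(values)))
  if (length(gene_ids) != ncol(values) || length(sample_ids) != nrow(values))
    stop_invalid("gene_ids/sample_ids lengths must match matrix dimensions")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, labels = labels,
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "expression_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.expression_set <- function(x) dim(x$values)

#' @export
print.expression_set <- function(x, ...) {
  cat("Expression set:", nrow(x$values), "samples x", ncol(x$values),
      "genes\n")
  tb <- table(factor(x$labels, levels = c(0, 1)))
  cat("Class counts: 0 =", tb[["0"]], ", 1 =", tb[["1"]], "\n")
  inf <- attr(x, "informative")
  if (!is.null(inf))
    cat("Synthetic informative genes:", length(inf), "\n")
  invisible(x)
}

#' Z-score normalize an expression matrix gene-wise
#'
#' Standardizes every gene (column) to mean 0 and population standard
#' deviation 1: `z = (x - mu) / sigma`, with `mu` and `sigma` computed over
#' all samples of that gene.  The population SD (divide by `n`) is used, not
#' the sample SD.  Zero-variance genes (flat probes) are mapped to all-zero
#' columns rather than raising; downstream feature selection can still
#' discard them.
#'
#' No clipping is applied: standardized values typically fall in about
#' \[-3, 3\] for roughly Gaussian genes but are not truncated to that range.
#'
#' @param ds an [expression_set()] or a bare numeric matrix (samples x genes).
#' @return An object of the same type with standardized values; gene means
#'   and SDs used are attached as attributes `center` and `scale`.
#' @export
#' @examples
#' zscore_normalize(matrix(c(1, 2, 3), ncol = 1))
zscore_normalize <- function(ds) {
  x <- if (inherits(ds, "expression_set")) ds$values else as.matrix(ds)
  if (length(x) == 0L || nrow(x) == 0L || ncol(x) == 0L)
    stop_invalid("cannot normalize an empty matrix")
  mu <- colMeans(x)
  z <- sweep(x, 2L, mu, "-")
  sigma <- sqrt(colMeans(z^2))          # population SD
  sigma[sigma < .Machine$double.eps^0.5 * pmax(1, abs(mu))] <- 0
  nz <- sigma > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sigma[nz], "/")
  z[, !nz] <- 0
  if (inherits(ds, "expression_set")) {
    out <- ds
    out$values <- z
    attr(out, "center") <- mu
    attr(out, "scale") <- sigma
    out
  } else structure(z, center = mu, scale = sigma)
}

#' Read a labelled expression matrix from delimited text
#'
#' Reads CSV/TSV (gzip-compressed files are handled transparently) into an
#' [expression_set()].  Files may store samples as rows (one label column)
#' or genes as rows (one label row named by `label`); the latter is
#' transposed on load.  Labels are coerced to `{0, 1}`: if the label values
#' are not already 0/1, the two observed values are mapped to 0 and 1 in
#' sorted order and the mapping is recorded in the `label_map` attribute.
#'
#' @param path file path.
#' @param orientation `"samples-rows"` (default) or `"genes-rows"`.
#' @param label name of the label column (or row, for `"genes-rows"`);
#'   default `"class"`.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @return An [expression_set()], with attribute `label_map` when labels
#'   were recoded.
#' @export
read_expression <- function(path, orientation = c("samples-rows", "genes-rows"),
                            label = "class", sep = ",") {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop_invalid("dataset file not found: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE, row.names = 1L)
  if (orientation == "genes-rows") {
    m <- t(as.matrix(df))
    df <- as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!label %in% colnames(df))
    stop_invalid("label column '", label, "' not found in ", path)
  raw_labels <- df[[label]]
  expr <- df[, setdiff(colnames(df), label), drop = FALSE]
  m <- suppressWarnings(
    vapply(expr, function(col) as.numeric(col), numeric(nrow(expr))))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(expr))
  dimnames(m) <- list(rownames(expr), setdiff(colnames(df), label))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_invalid("non-numeric or missing expression value at sample '",
                 rownames(m)[bad[1L]] %||% bad[1L], "', gene '",
                 colnames(m)[bad[2L]] %||% bad[2L], "'")
  }
  uv <- sort(unique(raw_labels))
  if (length(uv) > 2L)
    stop_invalid("label column has ", length(uv),
                 " distinct values; only binary classes are supported")
  label_map <- NULL
  if (!all(as.character(uv) %in% c("0", "1"))) {
    label_map <- setNames(seq_along(uv) - 1L, as.character(uv))
    labels <- label_map[as.character(raw_labels)]
  } else labels <- as.integer(as.character(raw_labels))
  out <- expression_set(m, labels)
  attr(out, "label_map") <- label_map
  out
}

#' Write an expression set to delimited text
#'
#' Inverse of [read_expression()] for the samples-as-rows orientation; the
#' label column is written last under the name given by `label`.
#'
#' @inheritParams read_expression
#' @param ds an [expression_set()].
#' @export
write_expression <- function(ds, path, label = "class", sep = ",") {
  stopifnot(inherits(ds, "expression_set"))
  df <- as.data.frame(ds$values, check.names = FALSE)
  df[[label]] <- ds$labels
  write.table(df, file = path, sep = sep, quote = FALSE,
              col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Generate a synthetic microarray-style dataset
#'
#' Emulates the shape of two-class microarray studies (genes far
#' outnumbering samples, imbalanced classes): every gene is standard normal
#' noise, except the first `n_informative` genes whose class-1 mean is
#' shifted by `shift` standard deviations.  The informative gene indices are
#' recorded in the `informative` attribute so that feature-selection recovery
#' can be scored.  The generator is a pure function of its arguments:
#' identical arguments produce bit-identical datasets.
#'
#' @param n_samples number of samples (rows).
#' @param n_genes number of genes (columns).
#' @param n_informative number of genes carrying a class-mean shift
#'   (must be `<= n_genes`).
#' @param shift class-1 mean shift on informative genes, in SD units.
#' @param class1_fraction fraction of samples assigned to class 1, in (0, 1).
#' @param seed integer seed.
#' @return An [expression_set()] with attribute `informative` (integer
#'   indices of the shifted genes).
#' @export
#' @examples
#' es <- synthetic_expression(20, 50, n_informative = 5, shift = 2, seed = 1)
#' attr(es, "informative")
synthetic_expression <- function(n_samples, n_genes, n_informative = 10,
                                 shift = 2, class1_fraction = 0.4, seed = 1) {
  if (n_informative > n_genes)
    stop_invalid("n_informative (", n_informative,
                 ") exceeds n_genes (", n_genes, ")")
  if (class1_fraction <= 0 || class1_fraction >= 1)
    stop_invalid("class1_fraction must lie strictly inside (0, 1)")
  if (n_samples < 2L) stop_invalid("need at least 2 samples")
  with_seed(seed, {
    n1 <- max(1L, min(n_samples - 1L, round(n_samples * class1_fraction)))
    labels <- c(rep(0L, n_samples - n1), rep(1L, n1))
    x <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes)
    if (n_informative > 0L)
      x[labels == 1L, seq_len(n_informative)] <-
        x[labels == 1L, seq_len(n_informative), drop = FALSE] + shift
    out <- expression_set(
      x, labels,
      gene_ids = paste0("gene_", seq_len(n_genes)),
      sample_ids = paste0("sample_", seq_len(n_samples)))
    attr(out, "informative") <-
      if (n_informative > 0L) seq_len(n_informative) else integer(0)
    out
  })
}
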