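#' Expression matrix container
#'
#' A light container for a gene-by-sample expression matrix together with its
#' normalization state. The state records where the values sit on the
#' counts -> log -> z-score processing path so that downstream consumers (most
#' importantly [compute_cma_score()], which expects z-scores) can refuse
#' inputs on the wrong scale.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty dimnames.
#' @param state One of `"counts"`, `"log"`, `"zscore"`.
#' @param metadata Free-form named list carried along unmodified.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `state` and `metadata`.
#' @examples
#' m <- matrix(rpois(6, 50), nrow = 3,
#'             dimnames = list(c("Lamp2a", "Hspa8", "Rara"), c("s1", "s2")))
#' em <- expr_matrix(m)
#' em$state
#' @export
expr_matrix <- function(values, state = c("counts", "log", "zscore"),
                        metadata = list()) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene (row) and sample (column) names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  structure(list(values = values, state = state, metadata = metadata),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from a delimited text file
#'
#' Reads a rectangular TSV/CSV table into an [expr_matrix()]. The first column
#' holds row labels; remaining columns must be numeric. Files written with
#' samples in rows can be read with `orientation = "genes_in_columns"`, which
#' transposes after reading so that the returned object is always
#' genes-by-samples.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @param state Normalization state to record; defaults to `"counts"`.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` -> comma, anything else -> tab).
#' @return An `expr_matrix`.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "genes_in_columns"),
                                   state = "counts", sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least one id column and one data column")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  num <- df[-1]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(names(num)[bad], collapse = ", "))
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "genes_in_columns") m <- t(m)
  expr_matrix(m, state = state,
              metadata = list(source = path, orientation = orientation))
}

#' Write an expression matrix to a delimited text file
#'
#' Writes genes in rows with a leading `gene_id` column, the inverse of
#' [read_expression_matrix()] so that write -> read is the identity on values,
#' dimnames and state (state is re-supplied by the caller on read).
#'
#' @param x An `expr_matrix`.
#' @param path Output path; `.csv` extension switches to comma separation.
#' @param sep Field separator override.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genes by across-sample interquartile range
#'
#' Keeps genes whose IQR across samples strictly exceeds `threshold`, the
#' variability filter commonly applied to expression arrays before signature
#' scoring (default threshold 0.5). Quartiles use linear interpolation between
#' order statistics (R's default, type 7), and gene order is preserved.
#'
#' @param x An `expr_matrix` with at least two samples.
#' @param threshold Non-negative IQR cutoff; genes with IQR > threshold are
#'   kept. Default 0.5.
#' @return An `expr_matrix` restricted to the kept genes. The number removed
#'   is recorded in `metadata$iqr_removed`.
#' @examples
#' m <- matrix(c(0, 0, 1, 1,  5, 5, 5, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("varies", "flat"), paste0("s", 1:4)))
#' iqr_filter(expr_matrix(m), 0.5)  # keeps "varies" only
#' @export
iqr_filter <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("'threshold' must be a single non-negative number")
  if (ncol(x$values) < 2) stop("IQR filtering needs at least 2 samples")
  iqr <- apply(x$values, 1, stats::IQR, type = 7)
  keep <- iqr > threshold
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$metadata$iqr_threshold <- threshold
  out$metadata$iqr_removed <- sum(!keep)
  out
}

#' Gene-wise z-score normalization
#'
#' Centers and scales each gene so that, across samples, it has mean 0 and
#' sample standard deviation 1 (n - 1 denominator). When
#' `reference_samples` is given, the per-gene center and scale are instead
#' estimated from those samples only (e.g. the vehicle group), so treated
#' samples are expressed in z-units relative to the reference distribution.
#' Zero-variance genes cannot be scaled and are set to all-zero with a
#' warning.
#'
#' @param x An `expr_matrix` with at least two samples.
#' @param log_first If `TRUE` and the state is `"counts"`, apply `log2(x + 1)`
#'   before scaling. Default `TRUE` for counts.
#' @param reference_samples Optional character vector of sample ids used to
#'   estimate each gene's center and scale; needs at least 2 samples.
#' @return An `expr_matrix` in state `"zscore"`.
#' @examples
#' m <- matrix(1:3, nrow = 1, dimnames = list("g", paste0("s", 1:3)))
#' zscore_normalize(expr_matrix(m, state = "log"))$values  # -1 0 1
#' @export
zscore_normalize <- function(x, log_first = NULL, reference_samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) stop("z-scoring needs at least 2 samples")
  if (x$state == "zscore")
    stop("matrix is already in zscore state")
  v <- x$values
  if (is.null(log_first)) log_first <- x$state == "counts"
  if (log_first) {
    if (x$state != "counts")
      stop("log_first only applies to matrices in 'counts' state")
    if (any(v < 0)) stop("negative values cannot be log-transformed")
    v <- log2(v + 1)
  }
  ref <- v
  if (!is.null(reference_samples)) {
    missing_ref <- setdiff(reference_samples, colnames(v))
    if (length(missing_ref))
      stop("reference sample(s) not in matrix: ",
           paste(missing_ref, collapse = ", "))
    if (length(reference_samples) < 2)
      stop("need at least 2 reference samples")
    ref <- v[, reference_samples, drop = FALSE]
  }
  ctr <- rowMeans(ref)
  scl <- apply(ref, 1, stats::sd)
  z <- (v - ctr) / scl
  flat <- scl == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to all-zero: ",
            paste(utils::head(rownames(v)[flat], 5), collapse = ", "))
    z[flat, ] <- 0
  }
  out <- x
  out$values <- z
  out$state <- "zscore"
  out$metadata$zscore_reference <- reference_samples
  out
}
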