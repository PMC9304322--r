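#' Compute the CMA activation index
#'
#' The CMA activation index of a sample is the weighted, direction-signed
#' average of the (z-scored) expression of the CMA network genes:
#' \deqn{S = \frac{\sum_i d_i\, w_i\, z_i}{\sum_i w_i}}
#' where \eqn{w_i > 0} is the weight of network gene \eqn{i} (2 for the
#' rate-limiting receptor LAMP2A, 1 otherwise), \eqn{d_i \in \{+1,-1\}} its
#' direction (whether the gene promotes or inhibits CMA) and \eqn{z_i} its
#' normalized expression in the sample. Both sums run over the network genes
#' actually present in the matrix; with `missing_policy = "renormalize"`
#' (default) absent genes simply drop out of numerator and denominator, with
#' `"error"` any absent gene aborts.
#'
#' @param matrix An [expr_matrix()] in `"zscore"` state (see
#'   [zscore_normalize()]). Set `allow_unnormalized = TRUE` to score other
#'   states at your own risk.
#' @param network A `cma_network` table (see [default_cma_network()]).
#' @param missing_policy `"renormalize"` (default) or `"error"`.
#' @param allow_unnormalized Skip the z-score state check.
#' @return A `cma_score_result` list with elements:
#'   \item{scores}{data frame `sample`, `score`, `n_genes_used`}
#'   \item{contributions}{genes-used x samples matrix of per-gene terms
#'     \eqn{d_i w_i z_i}}
#'   \item{genes_used, genes_missing}{character vectors partitioning the
#'     network genes}
#'   \item{weight_sum}{the normalizer \eqn{\sum w_i} over genes used}
#' @examples
#' net <- cma_network(c("LAMP2A", "HSPA8", "RARA"),
#'                    weight = c(2, 1, 1), direction = c(1, 1, -1))
#' z <- matrix(c(1, 0.5, 0.5), ncol = 1,
#'             dimnames = list(net$gene_id, "s1"))
#' compute_cma_score(expr_matrix(z, state = "zscore"), net)$scores$score
#' # (2*1 + 0.5 - 0.5) / 4 = 0.5
#' @export
compute_cma_score <- function(matrix, network,
                              missing_policy = c("renormalize", "error"),
                              allow_unnormalized = FALSE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(matrix, "expr_matrix"))
  network <- validate_cma_network(network)
  if (matrix$state != "zscore" && !allow_unnormalized)
    stop("matrix state is '", matrix$state,
         "'; the index is defined on z-scores (see zscore_normalize), ",
         "or pass allow_unnormalized = TRUE")
  present <- network$gene_id %in% rownames(matrix$values)
  genes_missing <- network$gene_id[!present]
  if (!any(present))
    stop("no network gene present in the expression matrix")
  if (missing_policy == "error" && length(genes_missing))
    stop("network gene(s) absent from matrix: ",
         paste(genes_missing, collapse = ", "))
  if (length(genes_missing))
    warning("renormalizing over ", sum(present), "/", nrow(network),
            " network genes; missing: ",
            paste(genes_missing, collapse = ", "))
  sub <- network[present, ]
  z <- matrix$values[sub$gene_id, , drop = FALSE]
  contrib <- z * (sub$direction * sub$weight)
  wsum <- sum(sub$weight)
  s <- colSums(contrib) / wsum
  structure(list(
    scores = data.frame(sample = colnames(z), score = as.numeric(s),
                        n_genes_used = nrow(sub),
                        stringsAsFactors = FALSE),
    contributions = contrib,
    genes_used = sub$gene_id,
    genes_missing = genes_missing,
    weight_sum = wsum
  ), class = "cma_score_result")
}

#' @export
print.cma_score_result <- function(x, ...) {
  cat(sprintf("CMA activation index: %d samples, %d/%d network genes used\n",
              nrow(x$scores), length(x$genes_used),
              length(x$genes_used) + length(x$genes_missing)))
  print(utils::head(x$scores, 10))
  invisible(x)
}

#' Per-group mean and standard error of CMA scores
#'
#' Aggregates per-sample scores into an ordered mean +/- SE series per
#' condition and timepoint, the form in which the index is tracked across,
#' e.g., organoid differentiation days. No hypothesis testing is performed.
#'
#' @param scores A `cma_score_result` from [compute_cma_score()].
#' @param grouping Data frame with columns `sample`, `condition`,
#'   `timepoint`; every scored sample must appear.
#' @return Data frame `condition`, `timepoint`, `n`, `mean`, `se`, ordered by
#'   condition then timepoint. `se` is `NA` for single-sample groups.
#' @export
score_trajectory <- function(scores, grouping) {
  stopifnot(inherits(scores, "cma_score_result"))
  req <- c("sample", "condition", "timepoint")
  missing_cols <- setdiff(req, names(grouping))
  if (length(missing_cols))
    stop("grouping is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- merge(scores$scores, grouping, by = "sample")
  ungrouped <- setdiff(scores$scores$sample, grouping$sample)
  if (length(ungrouped))
    stop("sample(s) without a group: ", paste(ungrouped, collapse = ", "))
  agg <- do.call(rbind, lapply(
    split(df, list(df$condition, df$timepoint), drop = TRUE),
    function(g) data.frame(condition = g$condition[1],
                           timepoint = g$timepoint[1],
                           n = nrow(g),
                           mean = mean(g$score),
                           se = if (nrow(g) > 1)
                             stats::sd(g$score) / sqrt(nrow(g)) else NA_real_,
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$condition, agg$timepoint), ]
  rownames(agg) <- NULL
  agg
}

#' Co-repressor to receptor expression ratio
#'
#' Per-sample ratio of two genes' expression on a linear scale, as used for
#' the NCOR1/RARA mRNA ratio that tracks the co-repressor tone on the
#' retinoic acid receptor axis. Samples where the denominator is not strictly
#' positive get `NA` with `flagged = TRUE` rather than being dropped.
#'
#' @param matrix An [expr_matrix()] in linear units (`"counts"` state, or any
#'   state with `allow_nonlinear = TRUE`).
#' @param numerator_gene,denominator_gene Gene ids present in the matrix
#'   (e.g. `"NCOR1"`, `"RARA"`).
#' @param groups Optional named vector or data frame (`sample`, `group`)
#'   carried through to the output.
#' @param allow_nonlinear Skip the linear-state check.
#' @return Data frame `sample`, `numerator`, `denominator`, `ratio`,
#'   `flagged` and optionally `group`.
#' @export
corepressor_receptor_ratio <- function(matrix, numerator_gene,
                                       denominator_gene, groups = NULL,
                                       allow_nonlinear = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$state != "counts" && !allow_nonlinear)
    stop("expression ratios need linear-scale values (state 'counts'); ",
         "pass allow_nonlinear = TRUE to override")
  for (g in c(numerator_gene, denominator_gene))
    if (!g %in% rownames(matrix$values))
      stop("gene '", g, "' not in matrix")
  num <- matrix$values[numerator_gene, ]
  den <- matrix$values[denominator_gene, ]
  flagged <- den <= 0
  ratio <- ifelse(flagged, NA_real_, num / den)
  out <- data.frame(sample = colnames(matrix$values),
                    numerator = as.numeric(num),
                    denominator = as.numeric(den),
                    ratio = as.numeric(ratio),
                    flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      out$group <- groups$group[match(out$sample, groups$sample)]
    } else {
      out$group <- unname(groups[out$sample])
    }
  }
  out
}
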