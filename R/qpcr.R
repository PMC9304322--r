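#' Relative quantification of qPCR data by the delta-delta-Ct method
#'
#' Converts a long-format Ct table into fold changes relative to a reference
#' group after normalization by a housekeeping gene (e.g. beta-actin).
#' Technical replicates are averaged per (sample, gene) before any
#' differencing. Then, per sample and target gene,
#' \deqn{\Delta Ct = Ct_{target} - Ct_{housekeeping}}
#' \deqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{reference}}
#' \deqn{fold = 2^{-\Delta\Delta Ct}}
#' assuming perfect amplification efficiency (doubling per cycle). By
#' construction the reference group's mean \eqn{\Delta\Delta Ct} is 0 per
#' gene, so its geometric-mean fold change is 1.
#'
#' @param ct Data frame with columns `sample`, `group`, `gene`, `ct` and
#'   optionally `replicate`. `ct` values are PCR cycle numbers (> 0).
#' @param housekeeping_gene Gene id used as the per-sample normalizer; must be
#'   measured in every sample.
#' @param reference_group Group label of the baseline condition (e.g.
#'   untreated); must be non-empty.
#' @return Data frame with one row per (sample, target gene):
#'   `sample`, `group`, `gene`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' ct <- data.frame(sample = rep(c("c1", "t1"), each = 2),
#'                  group  = rep(c("ctrl", "trt"), each = 2),
#'                  gene   = rep(c("Lamp2a", "Actb"), 2),
#'                  ct     = c(26, 20, 24, 20))
#' ddct_fold_change(ct, "Actb", "ctrl")  # treated fold = 4
#' @export
ddct_fold_change <- function(ct, housekeeping_gene, reference_group) {
  req <- c("sample", "group", "gene", "ct")
  missing_cols <- setdiff(req, names(ct))
  if (length(missing_cols))
    stop("Ct table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0")
  if (!any(ct$group == reference_group))
    stop("reference group '", reference_group, "' is empty")

  # replicate-first averaging: one Ct per (sample, gene)
  mean_ct <- stats::aggregate(ct ~ sample + group + gene, data = ct,
                              FUN = mean)
  hk <- mean_ct[mean_ct$gene == housekeeping_gene, ]
  no_hk <- setdiff(unique(mean_ct$sample), hk$sample)
  if (length(no_hk))
    stop("housekeeping gene '", housekeeping_gene,
         "' missing for sample(s): ", paste(no_hk, collapse = ", "))

  tgt <- mean_ct[mean_ct$gene != housekeeping_gene, ]
  if (!nrow(tgt)) stop("no target genes besides the housekeeping gene")
  tgt$delta_ct <- tgt$ct - hk$ct[match(tgt$sample, hk$sample)]

  ref_mean <- tapply(tgt$delta_ct[tgt$group == reference_group],
                     tgt$gene[tgt$group == reference_group], mean)
  no_ref <- setdiff(unique(tgt$gene), names(ref_mean))
  if (length(no_ref))
    stop("gene(s) not measured in the reference group: ",
         paste(no_ref, collapse = ", "))
  tgt$delta_delta_ct <- as.numeric(tgt$delta_ct - ref_mean[tgt$gene])
  tgt$fold <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$sample),
             c("sample", "group", "gene", "delta_ct", "delta_delta_ct",
               "fold")]
  rownames(out) <- NULL
  out
}
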