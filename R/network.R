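#' Build and validate a CMA network table
#'
#' The CMA activation index is computed over a table of network genes, each
#' carrying a positive weight and a direction (+1 for genes whose expression
#' promotes CMA, -1 for inhibitors). LAMP2A, the rate-limiting lysosomal
#' receptor, conventionally carries weight 2; every other component weight 1.
#'
#' @param genes Character vector of unique gene ids.
#' @param weight Positive numeric weights, recycled if length 1.
#' @param direction Integer +1 or -1 per gene, recycled if length 1.
#' @param note Optional free-text role annotation per gene.
#' @return A `cma_network` data frame with columns `gene_id`, `weight`,
#'   `direction`, `note`.
#' @seealso [default_cma_network()], [load_network_table()]
#' @export
cma_network <- function(genes, weight = 1, direction = 1,
                        note = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("network needs at least one gene")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene id(s) in network: ", paste(dup, collapse = ", "))
  tab <- data.frame(gene_id = genes,
                    weight = rep_len(as.numeric(weight), length(genes)),
                    direction = rep_len(as.numeric(direction), length(genes)),
                    note = rep_len(as.character(note), length(genes)),
                    stringsAsFactors = FALSE)
  validate_cma_network(tab)
}

validate_cma_network <- function(tab) {
  req <- c("gene_id", "weight", "direction")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("network table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"note" %in% names(tab)) tab$note <- ""
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    stop("duplicate gene id(s) in network: ", paste(dup, collapse = ", "))
  if (any(!is.finite(tab$weight)) || any(tab$weight <= 0))
    stop("network weights must be positive")
  if (!all(tab$direction %in% c(-1, 1)))
    stop("network directions must be +1 or -1")
  tab <- tab[c("gene_id", "weight", "direction", "note")]
  class(tab) <- c("cma_network", "data.frame")
  tab
}

#' Load a CMA network table from a TSV file
#'
#' Expects tab-separated columns `gene_id`, `weight`, `direction` and
#' optionally `note`; the table is validated (positive weights, directions
#' +1/-1, unique gene ids).
#'
#' @param path Path to the TSV file.
#' @return A validated `cma_network` data frame.
#' @export
load_network_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_cma_network(tab)
}

#' Write a CMA network table to a TSV file
#'
#' @param network A `cma_network` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_table <- function(network, path) {
  network <- validate_cma_network(network)
  utils::write.table(network, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Illustrative 17-component CMA network
#'
#' Returns the network table shipped with the package: 17 CMA effectors and
#' regulators with LAMP2A at weight 2 (rate-limiting receptor) and all other
#' components at weight 1, signed +1 for genes promoting CMA and -1 for
#' inhibitors (the RARA axis and other negative regulators).
#'
#' This membership/direction table is an *editable example* assembled from
#' the CMA literature for demonstration and testing: only the weighting rule
#' (LAMP2A 2, others 1) and the sign convention are fixed by the index
#' definition. Studies should substitute their own curated table via
#' [load_network_table()]. NCOR1 is deliberately not a member: it modulates
#' CMA through the RARA axis rather than as a network component, and is
#' analyzed separately through [corepressor_receptor_ratio()].
#'
#' @return A `cma_network` data frame with 17 rows.
#' @examples
#' net <- default_cma_network()
#' net[net$gene_id == "LAMP2A", ]
#' @export
default_cma_network <- function() {
  path <- system.file("extdata", "cma_network_17.tsv", package = "cmaquant",
                      mustWork = TRUE)
  load_network_table(path)
}
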