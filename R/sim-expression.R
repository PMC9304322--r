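#' Simulate a treated-vs-control expression dataset over a CMA network
#'
#' Generates a gene-by-sample matrix emulating a two-group design in which a
#' treatment shifts a chosen subset of network genes by stated effect sizes.
#' Per gene, samples are drawn around a log-scale Gaussian baseline
#' (`x = mu_g + sd_g * eps`, `eps ~ N(0,1)`); treated samples receive an
#' additional shift of `effects[gene]` *z-units*, i.e. `effects[gene] * sd_g`
#' on the log scale. Because effects are defined post-normalization, the
#' expected CMA-score difference between groups has the closed form
#' `sum(d_i w_i shift_i) / sum(w_i)` on the truth-normalized z matrix.
#'
#' Two matrices are returned: the raw log-scale matrix (`matrix`, state
#' `"log"`, for exercising the empirical normalization path) and the
#' truth-normalized z matrix (`zmatrix`, state `"zscore"`, each gene scaled
#' by its *true* baseline mean and SD, so programmed z-shifts are recovered
#' without estimation bias).
#'
#' @param network A `cma_network` table; its genes form the matrix rows.
#' @param n_control,n_treated Group sizes, each at least 2.
#' @param effects Named numeric vector of z-unit shifts applied to treated
#'   samples. Names not in the network are appended as extra (non-network)
#'   genes.
#' @param noise_sd Per-gene Gaussian noise SD (scalar or per-gene vector),
#'   strictly positive. Default 1.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param baseline_mean,baseline_sd Mean and SD of the per-gene log-scale
#'   baselines, drawn once from the seed. Defaults 8 and 2.
#' @return List with elements `matrix` (log-scale [expr_matrix()]), `zmatrix`
#'   (truth-normalized z-score `expr_matrix`), and `truth` (list:
#'   `gene_effects`, `group_labels`, `noise_sd`, `baselines`, `seed`).
#' @examples
#' net <- default_cma_network()
#' ds <- generate_expression_dataset(net, 5, 5,
#'                                   effects = c(LAMP2A = 1), seed = 1)
#' dim(ds$matrix)
#' @export
generate_expression_dataset <- function(network, n_control, n_treated,
                                        effects = numeric(0), noise_sd = 1,
                                        seed = 1, baseline_mean = 8,
                                        baseline_sd = 2) {
  network <- validate_cma_network(network)
  if (n_control < 2 || n_treated < 2)
    stop("group sizes must be at least 2")
  if (any(noise_sd <= 0)) stop("noise_sd must be strictly positive")
  if (length(effects) && is.null(names(effects)))
    stop("'effects' must be a named vector of gene -> z-shift")

  genes <- union(network$gene_id, names(effects))
  n_genes <- length(genes)
  noise_sd <- rep_len(noise_sd, n_genes)
  names(noise_sd) <- genes
  shift <- stats::setNames(numeric(n_genes), genes)
  shift[names(effects)] <- effects

  samples <- c(sprintf("ctrl_%02d", seq_len(n_control)),
               sprintf("trt_%02d", seq_len(n_treated)))
  groups <- stats::setNames(rep(c("control", "treated"),
                                c(n_control, n_treated)), samples)
  treated <- groups == "treated"

  withr_seed <- function(expr) { # local RNG scope, pure in `seed`
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
  }
  res <- withr_seed({
    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    eps <- matrix(stats::rnorm(n_genes * length(samples)), n_genes)
    list(mu = mu, eps = eps)
  })
  mu <- stats::setNames(res$mu, genes)
  z <- res$eps + outer(shift, as.numeric(treated))
  x <- mu + noise_sd * z
  dimnames(x) <- dimnames(z) <- list(genes, samples)

  truth <- list(gene_effects = shift, group_labels = groups,
                noise_sd = noise_sd,
                baselines = data.frame(gene_id = genes, mean = mu,
                                       sd = noise_sd, row.names = NULL),
                seed = seed)
  list(matrix = expr_matrix(x, state = "log",
                            metadata = list(simulated = TRUE, seed = seed)),
       zmatrix = expr_matrix(z, state = "zscore",
                             metadata = list(simulated = TRUE, seed = seed,
                                             normalization = "true baseline")),
       truth = truth)
}

#' Write a simulated expression dataset to disk
#'
#' Writes the log-scale matrix as TSV (genes in rows) plus a JSON truth
#' sidecar (`<prefix>_truth.json`) holding effects, group labels and
#' baselines, so downstream analyses can be audited without rerunning the
#' generator.
#'
#' @param dataset Result of [generate_expression_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, default `"expr"`.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_expression_dataset <- function(dataset, dir, prefix = "expr") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat_path <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_expression_matrix(dataset$matrix, mat_path)
  jsonlite::write_json(
    list(gene_effects = as.list(dataset$truth$gene_effects),
         group_labels = as.list(dataset$truth$group_labels),
         noise_sd = as.list(dataset$truth$noise_sd),
         baselines = dataset$truth$baselines,
         seed = dataset$truth$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(matrix = mat_path, truth = truth_path))
}
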