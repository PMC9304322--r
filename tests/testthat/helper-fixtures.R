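# shared fixtures and small utilities for the suite

# 3-gene network of the worked score example
worked_network <- function() {
  cma_network(c("LAMP2A", "HSPA8", "RARA"),
              weight = c(2, 1, 1), direction = c(1, 1, -1))
}

# z-score matrix builder with dimnames
zmat <- function(values, genes, samples = paste0("s", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, state = "zscore")
}

# random small network + matching z matrix, used by property tests
random_score_case <- function(n_genes = sample(4:12, 1), n_samples = 3) {
  genes <- paste0("G", seq_len(n_genes))
  net <- cma_network(genes,
                     weight = stats::runif(n_genes, 0.5, 3),
                     direction = sample(c(-1, 1), n_genes, replace = TRUE))
  z <- matrix(stats::rnorm(n_genes * n_samples), n_genes)
  list(net = net, em = zmat(z, genes))
}

# per-detected-cell true puncta count, matched by nearest nucleus centroid
truth_counts_for <- function(cells, truth_cells) {
  vapply(seq_len(nrow(cells)), function(i) {
    j <- which.min((truth_cells$row - cells$row[i])^2 +
                     (truth_cells$col - cells$col[i])^2)
    truth_cells$n_puncta[j]
  }, numeric(1))
}

# aggregate detector performance over seeded synthetic fields
puncta_benchmark <- function(seeds, snr, n_cells = 12,
                             image_shape = c(320, 320),
                             puncta_law = list(type = "poisson", mean = 4)) {
  ok <- 0L; tot <- 0L; tp <- 0L; fp <- 0L; fn <- 0L
  for (s in seeds) {
    fld <- generate_reporter_field(n_cells, puncta_law = puncta_law,
                                   snr = snr, image_shape = image_shape,
                                   seed = s)
    res <- quantify_reporter_field(fld$nuclei, fld$reporter)
    tc <- truth_counts_for(res$cells, fld$truth$cells)
    tot <- tot + nrow(res$cells)
    ok <- ok + sum(res$cells$puncta_count == tc)
    pm <- match_puncta(attr(res$cells, "puncta"), fld$truth$puncta)
    tp <- tp + pm$tp; fp <- fp + pm$fp; fn <- fn + pm$fn
  }
  list(exact_fraction = ok / tot, precision = tp / (tp + fp),
       recall = tp / (tp + fn), n_cells = tot, n_puncta = tp + fn)
}
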