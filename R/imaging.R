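#' Segment nuclei from a single-channel image
#'
#' Thresholds the nuclei channel at `median + k * MAD` (a robust background
#' estimate), fills holes, splits touching nuclei by distance-transform
#' watershed, and removes regions below a minimum area. Returns an integer
#' label matrix (0 = background) with labels renumbered consecutively.
#'
#' @param img Numeric 2-D matrix (nuclei channel).
#' @param k Threshold in robust-SD units over the background (default 5).
#' @param min_area Minimum region area in pixels (default 30).
#' @param blur_sigma Gaussian pre-smoothing SD in pixels (default 1).
#' @return Integer label matrix of the same shape.
#' @examples
#' fld <- generate_reporter_field(5, seed = 2)
#' labs <- segment_nuclei(fld$nuclei)
#' max(labs)  # 5
#' @export
segment_nuclei <- function(img, k = 5, min_area = 30, blur_sigma = 1) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'img' must be a numeric 2-D matrix")
  sm <- img
  if (blur_sigma > 0) {
    sz <- 2 * ceiling(3 * blur_sigma) + 1
    sm <- as.matrix(EBImage::filter2(
      img, EBImage::makeBrush(sz, "gaussian", sigma = blur_sigma)))
  }
  thr <- stats::median(sm) + k * stats::mad(sm)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  labs <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labs <- as.matrix(EBImage::imageData(labs))
  areas <- tabulate(labs[labs > 0])
  keep <- which(areas >= min_area)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- labs > 0
  out[nz] <- relabel[labs[nz]]
  out
}

# centroid (row, col), area and equivalent radius per label
label_stats <- function(labels) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      radius = numeric(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  ri <- (idx - 1) %% nrow(labels) + 1
  ci <- (idx - 1) %/% nrow(labels) + 1
  area <- as.integer(tabulate(lab, n))
  data.frame(cell_id = seq_len(n),
             row = as.numeric(rowsum(ri, lab)) / area,
             col = as.numeric(rowsum(ci, lab)) / area,
             area = area,
             radius = sqrt(area / pi))
}

#' Gate reporter-expressing cells
#'
#' Estimates each cell's cytosol as an annulus around its nucleus and flags
#' the cell as expressing when its mean cytosolic reporter intensity exceeds
#' `background mean + k * background SD`. This implements the rule of
#' counting cells by nuclei but discounting nuclei without associated
#' cytosolic reporter fluorescence. Pixels contested between neighbouring
#' cells are assigned to the nearest nucleus centroid; the background mean
#' and SD are estimated robustly (median and MAD) from pixels beyond every
#' cell's reach.
#'
#' @param labels Integer nucleus label matrix from [segment_nuclei()].
#' @param reporter Numeric reporter-channel matrix, same shape.
#' @param k Gate stringency in background-SD units (default 3); `Inf` gates
#'   out every cell.
#' @param annulus_width Width in pixels of the gating annulus just outside
#'   the nucleus (default 5).
#' @param cyto_reach Outer extent in pixels of the cytosol region used
#'   later for puncta detection (default 5; kept short of the cell boundary
#'   so boundary gradients stay out of the detection band).
#' @return Data frame of cell records (`cell_id`, `row`, `col`, `area`,
#'   `radius`, `cyto_mean`, `expressing`), empty when there are no labels.
#'   Attributes: `masks` (per-cell pixel-index lists `annulus` and
#'   `cytosol`), `background` (mean, sd), `dim`.
#' @export
gate_expressing_cells <- function(labels, reporter, k = 3,
                                  annulus_width = 5, cyto_reach = 5) {
  if (!all(dim(labels) == dim(reporter)))
    stop("'labels' and 'reporter' must have the same shape")
  st <- label_stats(labels)
  n <- nrow(st)
  nr <- nrow(labels); nc <- ncol(labels)
  if (n == 0) {
    out <- data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      radius = numeric(0), cyto_mean = numeric(0),
                      expressing = logical(0))
    attr(out, "masks") <- list(annulus = list(), cytosol = list())
    attr(out, "background") <- c(mean = stats::median(reporter),
                                 sd = stats::mad(reporter))
    attr(out, "image_dim") <- dim(reporter)
    return(out)
  }
  # nearest-centroid assignment within each cell's reach
  best_d <- matrix(Inf, nr, nc)
  best_lab <- matrix(0L, nr, nc)
  reach <- st$radius + cyto_reach
  for (i in seq_len(n)) {
    R <- ceiling(reach[i]) + 1
    ri <- max(1, floor(st$row[i] - R)):min(nr, ceiling(st$row[i] + R))
    ci <- max(1, floor(st$col[i] - R)):min(nc, ceiling(st$col[i] + R))
    d <- sqrt(outer((ri - st$row[i])^2, (ci - st$col[i])^2, "+"))
    d[d > reach[i]] <- Inf
    win_d <- best_d[ri, ci, drop = FALSE]
    upd <- d < win_d
    win_d[upd] <- d[upd]
    best_d[ri, ci] <- win_d
    win_l <- best_lab[ri, ci, drop = FALSE]
    win_l[upd] <- i
    best_lab[ri, ci] <- win_l
  }
  # robust background: pixels beyond every cell's reach may still include
  # cell peripheries, so use median/MAD rather than mean/SD
  bg_idx <- which(best_lab == 0L)
  bg_px <- if (length(bg_idx) >= 50) reporter[bg_idx] else reporter
  bg_mean <- stats::median(bg_px)
  bg_sd <- stats::mad(bg_px)
  outside_nuc <- labels == 0L
  annulus <- vector("list", n)
  cytosol <- vector("list", n)
  cyto_mean <- numeric(n)
  for (i in seq_len(n)) {
    own <- best_lab == i & outside_nuc
    annulus[[i]] <- which(own & best_d > st$radius[i] &
                            best_d <= st$radius[i] + annulus_width)
    cytosol[[i]] <- which(own & best_d > st$radius[i] &
                            best_d <= st$radius[i] + cyto_reach)
    cyto_mean[i] <- if (length(annulus[[i]])) mean(reporter[annulus[[i]]])
                    else NA_real_
  }
  gate <- bg_mean + k * bg_sd
  out <- cbind(st, data.frame(cyto_mean = cyto_mean,
                              expressing = !is.na(cyto_mean) &
                                cyto_mean > gate))
  attr(out, "masks") <- list(annulus = annulus, cytosol = cytosol)
  attr(out, "background") <- c(mean = bg_mean, sd = bg_sd)
  attr(out, "image_dim") <- dim(reporter)
  out
}

# 5x5 grayscale maximum filter by shifting (replicated borders)
max_filter_5x5 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    m[ri, ci, drop = FALSE]
  }
  out <- x
  for (dr in -2:2) for (dc in -2:2)
    if (dr || dc) out <- pmax(out, shift(x, dr, dc))
  out
}

#' Detect reporter puncta within gated cells
#'
#' Band-pass (difference-of-Gaussians) blob detection restricted to each
#' expressing cell's cytosol mask. A punctum is a local maximum of the DoG
#' response exceeding `rel_threshold` times the response-scale noise SD of
#' that cell's cytosol. The noise SD is estimated robustly from adjacent-
#' pixel differences of the raw reporter within the mask (MAD / sqrt(2)),
#' then converted to response units through the exact L2 gain of the DoG
#' kernel — a threshold relative to local background noise, so counts are
#' invariant to multiplicative intensity scaling. Maxima closer than
#' `min_sep` pixels are merged (strongest kept). Non-expressing cells are
#' excluded before counting and report 0 by convention.
#'
#' @param reporter Numeric reporter-channel matrix.
#' @param cells Cell records from [gate_expressing_cells()] (with masks).
#' @param sigma DoG inner scale in pixels, in \[0.5, 10\] (default 1.5:
#'   slightly below the spot width, which preserves the resolution of
#'   close punctum pairs at a small cost in peak response; outer scale is
#'   `2 * sigma`).
#' @param rel_threshold Detection threshold in robust-SD units, in
#'   \[1, 50\] (default 5).
#' @param min_sep Minimum separation between puncta in pixels (default 4).
#' @return The `cells` data frame with a `puncta_count` column appended;
#'   attribute `puncta` holds a data frame of detections (`cell_id`, `row`,
#'   `col`, `response`).
#' @export
detect_puncta <- function(reporter, cells, sigma = 1.5, rel_threshold = 5,
                          min_sep = 4) {
  if (sigma < 0.5 || sigma > 10)
    stop("'sigma' out of the documented range [0.5, 10]")
  if (rel_threshold < 1 || rel_threshold > 50)
    stop("'rel_threshold' out of the documented range [1, 50]")
  masks <- attr(cells, "masks")
  if (is.null(masks)) stop("'cells' must come from gate_expressing_cells()")
  sz2 <- 2 * ceiling(6 * sigma) + 1
  k1 <- EBImage::makeBrush(sz2, "gaussian", sigma = sigma)
  k2 <- EBImage::makeBrush(sz2, "gaussian", sigma = 2 * sigma)
  b1 <- as.matrix(EBImage::filter2(reporter, k1))
  b2 <- as.matrix(EBImage::filter2(reporter, k2))
  resp <- b1 - b2
  kernel_gain <- sqrt(sum((k1 - k2)^2)) # response SD per unit pixel noise SD
  is_max <- resp >= max_filter_5x5(resp)
  nr <- nrow(reporter)
  npix <- length(reporter)
  counts <- integer(nrow(cells))
  hits <- list()
  for (i in seq_len(nrow(cells))) {
    if (!isTRUE(cells$expressing[i])) next
    idx <- masks$cytosol[[i]]
    if (!length(idx)) next
    # pixel noise from vertical neighbour differences inside the mask
    in_mask <- logical(npix)
    in_mask[idx] <- TRUE
    ok <- (idx %% nr) != 0 & in_mask[pmin(idx + 1, npix)]
    noise_sd <- if (sum(ok) >= 30)
      stats::mad(reporter[idx[ok]] - reporter[idx[ok] + 1]) / sqrt(2)
    else stats::mad(resp[idx]) / kernel_gain
    thr <- rel_threshold * noise_sd * kernel_gain
    cand <- idx[is_max[idx] & resp[idx] > thr]
    if (!length(cand)) next
    rr <- (cand - 1) %% nr + 1
    cc <- (cand - 1) %/% nr + 1
    ord <- order(resp[cand], decreasing = TRUE)
    keep <- integer(0)
    for (j in ord) {
      if (!length(keep) ||
          all((rr[j] - rr[keep])^2 + (cc[j] - cc[keep])^2 >= min_sep^2))
        keep <- c(keep, j)
    }
    counts[i] <- length(keep)
    hits[[length(hits) + 1]] <-
      data.frame(cell_id = cells$cell_id[i], row = rr[keep], col = cc[keep],
                 response = resp[cand][keep])
  }
  out <- cells
  out$puncta_count <- counts
  pt <- if (length(hits)) do.call(rbind, hits) else
    data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
               response = numeric(0))
  rownames(pt) <- NULL
  attr(out, "masks") <- masks
  attr(out, "background") <- attr(cells, "background")
  attr(out, "image_dim") <- attr(cells, "image_dim")
  attr(out, "puncta") <- pt
  out
}

#' Match detected puncta against ground truth
#'
#' Greedy nearest-neighbour matching of detections to true puncta within a
#' pixel tolerance; each truth punctum can be claimed once. Used to score
#' the detector on synthetic fields.
#'
#' @param detected Data frame with `row`, `col` (e.g. the `puncta` attribute
#'   of [detect_puncta()] output).
#' @param truth Data frame with `row`, `col` (the generator's ground truth).
#' @param tol Match radius in pixels (default 3).
#' @return List: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
match_puncta <- function(detected, truth, tol = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(tp = 0L, fp = nd, fn = nt,
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_))
  d2 <- outer(detected$row, truth$row, "-")^2 +
        outer(detected$col, truth$col, "-")^2
  used <- logical(nt)
  tp <- 0L
  for (i in seq_len(nd)) {
    j <- which.min(ifelse(used, Inf, d2[i, ]))
    if (!used[j] && d2[i, j] <= tol^2) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       precision = tp / nd, recall = tp / nt)
}

#' Classify CMA-positive cells from per-cell puncta counts
#'
#' A cell is CMA-positive when its puncta count strictly exceeds the
#' threshold (default 3, i.e. 4 or more puncta). The percentage is computed
#' over the supplied (expressing) cells.
#'
#' @param counts Integer vector of per-cell puncta counts; must be
#'   non-empty.
#' @param threshold Strict count threshold (default 3).
#' @return List: `positive` (logical vector), `percent_positive`.
#' @examples
#' classify_cma_positive(c(0, 2, 4, 5, 3))$percent_positive  # 40
#' @export
classify_cma_positive <- function(counts, threshold = 3) {
  if (!length(counts)) stop("empty cell list")
  if (any(counts < 0)) stop("puncta counts must be >= 0")
  pos <- counts > threshold
  list(positive = pos, percent_positive = 100 * mean(pos))
}

#' Field-level quality control by nuclei count
#'
#' A field passes QC when it contains at least `fraction` (default 1/10) of
#' the mean nuclei count of the control (untreated) fields — the exclusion
#' rule that guards against out-of-focus fields after drug-induced changes
#' in cell volume or adherence. The boundary is inclusive.
#'
#' @param fields List of field results (see [quantify_reporter_field()]) or
#'   a numeric vector of nuclei counts.
#' @param control_fields Control fields in the same form; must be non-empty.
#' @param fraction QC fraction of the control mean (default 0.1).
#' @return If `fields` is a list of field results, the same list with
#'   `qc_pass` set; if numeric, a logical vector.
#' @examples
#' field_qc(c(10, 9), control_fields = c(100, 100))  # TRUE FALSE
#' @export
field_qc <- function(fields, control_fields, fraction = 0.1) {
  get_n <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(f) as.numeric(f$n_nuclei), numeric(1))
  }
  ctrl_n <- get_n(control_fields)
  if (!length(ctrl_n)) stop("empty control field set")
  cutoff <- fraction * mean(ctrl_n)
  pass <- get_n(fields) >= cutoff
  if (is.numeric(fields)) return(pass)
  for (i in seq_along(fields)) fields[[i]]$qc_pass <- pass[i]
  fields
}

#' Classify tandem-reporter puncta into autophagosomes and autolysosomes
#'
#' For a tandem mCherry-GFP flux reporter, puncta detected on the red
#' channel are dual-fluorescent (autophagosomes) when their green intensity
#' exceeds the green background gate, and red-only (autolysosomes, GFP
#' quenched at lysosomal pH) otherwise.
#'
#' @param red_channel,green_channel Aligned numeric matrices.
#' @param puncta Data frame of punctum locations (`row`, `col`), typically
#'   the `puncta` attribute of [detect_puncta()] run on the red channel.
#' @param k Green gate in robust-SD units over the green background
#'   (default 3).
#' @param radius Radius in pixels of the disk over which punctum green
#'   intensity is averaged (default 2).
#' @return List: `n_dual`, `n_red_only`, `flux_ratio` (autolysosome
#'   fraction, `NA` with zero puncta), `per_punctum` (input plus `dual`
#'   flag). `n_dual + n_red_only` always equals `nrow(puncta)`.
#' @export
classify_tandem_puncta <- function(red_channel, green_channel, puncta,
                                   k = 3, radius = 2) {
  if (!all(dim(red_channel) == dim(green_channel)))
    stop("channel shapes are misaligned")
  n <- nrow(puncta)
  if (n == 0)
    return(list(n_dual = 0L, n_red_only = 0L, flux_ratio = NA_real_,
                per_punctum = cbind(puncta, dual = logical(0))))
  gate <- stats::median(green_channel) + k * stats::mad(green_channel)
  nr <- nrow(green_channel); nc <- ncol(green_channel)
  green_at <- vapply(seq_len(n), function(j) {
    ri <- max(1, round(puncta$row[j]) - radius):
          min(nr, round(puncta$row[j]) + radius)
    ci <- max(1, round(puncta$col[j]) - radius):
          min(nc, round(puncta$col[j]) + radius)
    d2 <- outer((ri - puncta$row[j])^2, (ci - puncta$col[j])^2, "+")
    mean(green_channel[ri, ci][d2 <= radius^2])
  }, numeric(1))
  dual <- green_at > gate
  list(n_dual = sum(dual), n_red_only = sum(!dual),
       flux_ratio = sum(!dual) / n,
       per_punctum = cbind(puncta, dual = dual))
}

#' Quantify a reporter field end to end
#'
#' Convenience wrapper running nuclei segmentation, expressing-cell gating,
#' puncta detection and CMA-positive classification on one two-channel
#' field.
#'
#' @param nuclei,reporter Channel matrices.
#' @param field_id Field identifier.
#' @param cma_threshold Strict puncta threshold for CMA-positivity
#'   (default 3).
#' @param gate_k,annulus_width,cyto_reach Passed to
#'   [gate_expressing_cells()].
#' @param sigma,rel_threshold,min_sep Passed to [detect_puncta()].
#' @param seg_k,min_area Passed to [segment_nuclei()].
#' @return A `field_result` list: `field_id`, `n_nuclei`, `n_expressing`,
#'   `cells` (with `puncta_count` and `cma_positive`), `mean_puncta` (over
#'   expressing cells), `percent_cma_positive`, `qc_pass` (`NA` until
#'   [field_qc()] is applied).
#' @export
quantify_reporter_field <- function(nuclei, reporter, field_id = "field",
                                    cma_threshold = 3, gate_k = 3,
                                    annulus_width = 5, cyto_reach = 5,
                                    sigma = 1.5, rel_threshold = 5,
                                    min_sep = 4, seg_k = 5, min_area = 30) {
  labels <- segment_nuclei(nuclei, k = seg_k, min_area = min_area)
  cells <- gate_expressing_cells(labels, reporter, k = gate_k,
                                 annulus_width = annulus_width,
                                 cyto_reach = cyto_reach)
  cells <- detect_puncta(reporter, cells, sigma = sigma,
                         rel_threshold = rel_threshold, min_sep = min_sep)
  expr_counts <- cells$puncta_count[cells$expressing]
  if (length(expr_counts)) {
    cls <- classify_cma_positive(expr_counts, cma_threshold)
    cells$cma_positive <- FALSE
    cells$cma_positive[cells$expressing] <- cls$positive
    pct <- cls$percent_positive
    mp <- mean(expr_counts)
  } else {
    cells$cma_positive <- logical(nrow(cells))
    pct <- NA_real_
    mp <- NA_real_
  }
  structure(list(field_id = field_id, n_nuclei = nrow(cells),
                 n_expressing = sum(cells$expressing), cells = cells,
                 mean_puncta = mp, percent_cma_positive = pct,
                 qc_pass = NA),
            class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf(
    "field %s: %d nuclei, %d expressing, mean %.2f puncta/cell, %.1f%% CMA+%s\n",
    x$field_id, x$n_nuclei, x$n_expressing,
    ifelse(is.na(x$mean_puncta), NaN, x$mean_puncta),
    ifelse(is.na(x$percent_cma_positive), NaN, x$percent_cma_positive),
    if (is.na(x$qc_pass)) "" else
      if (x$qc_pass) " [QC pass]" else " [QC FAIL]"))
  invisible(x)
}
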