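#' Simulate a multichannel KFERQ-reporter image field with ground truth
#'
#' Renders a two-channel field emulating high-content acquisition of a
#' photoswitchable CMA reporter: channel 1 holds nuclei (bright disks),
#' channel 2 the reporter (diffuse cytosolic signal in expressing cells plus
#' symmetric-Gaussian puncta). Every rendered object is listed in the
#' returned ground truth, so segmentation, gating and puncta detection can be
#' scored exactly.
#'
#' Geometry: nucleus centers are placed by dart-throwing with a
#' minimum-distance constraint so cells never overlap; each cell is the disk
#' of radius `nucleus_radius + cyto_width` around its nucleus, and its
#' cytosol the annulus between nucleus and cell edge. Puncta are Gaussian
#' spots of width `punctum_sigma` placed inside the cytosol annulus with a
#' minimum mutual separation. SNR is defined as
#' (punctum peak - cytosol mean) / noise SD.
#'
#' @param n_cells Number of cells to place (0 gives blank channels and empty
#'   truth).
#' @param puncta_law Puncta count per expressing cell: a single integer
#'   (fixed count), a vector of length `n_cells`, or
#'   `list(type = "poisson", mean = lambda)`.
#' @param expressing_fraction Fraction of cells expressing the reporter, in
#'   \[0, 1\]. Non-expressing cells get no cytosolic reporter signal.
#' @param snr Punctum peak amplitude over the diffuse cytosol, in units of
#'   the noise SD; must be > 0.
#' @param image_shape Integer (rows, cols) of the field. Default c(256, 256).
#' @param seed Integer seed; generation is a pure function of its arguments.
#' @param field_id Identifier carried into the truth record.
#' @param nucleus_radius,cyto_width Cell geometry in pixels (defaults 7, 14).
#' @param punctum_sigma Gaussian spot SD in pixels (default 2).
#' @param bg_level,nucleus_level,cyto_level Mean intensities (arbitrary
#'   16-bit-range counts) of background, nuclei and diffuse cytosol.
#' @param noise_sd Gaussian read-noise SD added to both channels.
#' @param pixel_size Physical pixel size in micrometres, recorded in truth.
#' @param min_puncta_sep Minimum distance between puncta of one cell (px).
#' @return List with `nuclei` and `reporter` intensity matrices and `truth`,
#'   a list with `cells` (data frame: `cell_id`, `row`, `col`, `expressing`,
#'   `n_puncta`), `puncta` (data frame: `cell_id`, `row`, `col`), and the
#'   generation parameters. Coordinates are 1-based R indices; JSON export
#'   via [write_reporter_field()] converts to 0-based.
#' @examples
#' fld <- generate_reporter_field(10, puncta_law = 4, seed = 1)
#' fld$truth$cells$n_puncta
#' @export
generate_reporter_field <- function(n_cells, puncta_law = 4,
                                    expressing_fraction = 1, snr = 8,
                                    image_shape = c(256, 256), seed = 1,
                                    field_id = "field_1",
                                    nucleus_radius = 7, cyto_width = 14,
                                    punctum_sigma = 2,
                                    bg_level = 200, nucleus_level = 3000,
                                    cyto_level = 400, noise_sd = 60,
                                    pixel_size = 0.5, min_puncta_sep = 6) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (snr <= 0) stop("snr must be > 0")
  if (expressing_fraction < 0 || expressing_fraction > 1)
    stop("expressing_fraction must be in [0, 1]")
  nr <- image_shape[1]; nc <- image_shape[2]
  cell_r <- nucleus_radius + cyto_width

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  # dart-throwing placement: disjoint cells with a small gap
  min_dist <- 2 * cell_r + 3
  margin <- cell_r + 2
  if (n_cells > 0 && (nr <= 2 * margin || nc <= 2 * margin))
    stop("image too small for the requested cell geometry")
  centers <- matrix(numeric(0), ncol = 2)
  attempts <- 0
  max_attempts <- max(200 * n_cells, 1000)
  while (nrow(centers) < n_cells) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("infeasible packing: could not place ", n_cells,
           " cells of radius ", cell_r, " in a ", nr, "x", nc, " field")
    cand <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >=
            min_dist))
      centers <- rbind(centers, cand)
  }

  expressing <- logical(n_cells)
  if (n_cells > 0) {
    n_expr <- round(expressing_fraction * n_cells)
    expressing[sample.int(n_cells, n_expr)] <- TRUE
  }

  # puncta counts per cell
  n_puncta <- integer(n_cells)
  if (n_cells > 0) {
    if (is.list(puncta_law)) {
      if (!identical(puncta_law$type, "poisson"))
        stop("unknown puncta_law type: ", puncta_law$type)
      n_puncta <- stats::rpois(n_cells, puncta_law$mean)
    } else {
      n_puncta <- rep_len(as.integer(puncta_law), n_cells)
    }
    n_puncta[!expressing] <- 0L
  }

  # place puncta inside the cytosol, clear of the cell boundary (the
  # boundary step would otherwise leak into band-pass detection)
  r_lo <- nucleus_radius + punctum_sigma + 1
  r_hi <- cell_r - 4 * punctum_sigma - 0.5
  if (n_cells > 0 && any(n_puncta > 0) && r_hi <= r_lo)
    stop("cytosol annulus too narrow for puncta of this width")
  puncta <- list()
  for (i in seq_len(n_cells)) {
    k <- n_puncta[i]
    if (k == 0) next
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(pts) < k && tries <= 500 * k) {
      tries <- tries + 1
      rad <- stats::runif(1, r_lo, r_hi)
      ang <- stats::runif(1, 0, 2 * pi)
      p <- centers[i, ] + rad * c(cos(ang), sin(ang))
      if (nrow(pts) == 0 ||
          all(sqrt(rowSums((pts - rep(p, each = nrow(pts)))^2)) >=
              min_puncta_sep))
        pts <- rbind(pts, p)
    }
    if (nrow(pts) < k) {
      # dense cell: fall back to an evenly spaced ring at mid-band radius,
      # randomly rotated, which guarantees the separation up to the
      # circumference limit
      mid <- (r_lo + r_hi) / 2
      if (2 * mid * sin(pi / k) < min_puncta_sep)
        stop("cannot place ", k, " puncta with separation ",
             min_puncta_sep, " in one cytosol; reduce the count or the ",
             "separation")
      rot <- stats::runif(1, 0, 2 * pi)
      ang <- rot + 2 * pi * (seq_len(k) - 1) / k
      pts <- cbind(centers[i, 1] + mid * cos(ang),
                   centers[i, 2] + mid * sin(ang))
    }
    puncta[[length(puncta) + 1]] <-
      data.frame(cell_id = i, row = pts[, 1], col = pts[, 2])
  }
  puncta <- if (length(puncta)) do.call(rbind, puncta) else
    data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0))

  # render
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  nuclei_img <- matrix(bg_level, nr, nc)
  reporter_img <- matrix(bg_level, nr, nc)
  amp <- snr * noise_sd
  for (i in seq_len(n_cells)) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    nuclei_img[d2 <= nucleus_radius^2] <- bg_level + nucleus_level
    if (expressing[i])
      reporter_img[d2 <= cell_r^2] <- reporter_img[d2 <= cell_r^2] +
        cyto_level
  }
  if (nrow(puncta)) {
    half <- ceiling(4 * punctum_sigma)
    for (j in seq_len(nrow(puncta))) {
      r0 <- puncta$row[j]; c0 <- puncta$col[j]
      ri <- max(1, floor(r0 - half)):min(nr, ceiling(r0 + half))
      ci <- max(1, floor(c0 - half)):min(nc, ceiling(c0 + half))
      spot <- amp * exp(-(outer((ri - r0)^2, (ci - c0)^2, "+")) /
                          (2 * punctum_sigma^2))
      reporter_img[ri, ci] <- reporter_img[ri, ci] + spot
    }
  }
  nuclei_img <- nuclei_img + stats::rnorm(nr * nc, 0, noise_sd)
  reporter_img <- reporter_img + stats::rnorm(nr * nc, 0, noise_sd)
  nuclei_img <- pmin(pmax(nuclei_img, 0), 65535)
  reporter_img <- pmin(pmax(reporter_img, 0), 65535)

  cells <- data.frame(cell_id = seq_len(n_cells),
                      row = if (n_cells) centers[, 1] else numeric(0),
                      col = if (n_cells) centers[, 2] else numeric(0),
                      expressing = expressing,
                      n_puncta = n_puncta)
  list(nuclei = nuclei_img, reporter = reporter_img,
       truth = list(cells = cells, puncta = puncta, field_id = field_id,
                    pixel_size = pixel_size, seed = seed,
                    nucleus_radius = nucleus_radius, cyto_width = cyto_width,
                    punctum_sigma = punctum_sigma, snr = snr,
                    noise_sd = noise_sd, bg_level = bg_level,
                    cyto_level = cyto_level))
}

#' Write a simulated reporter field as 16-bit TIFF plus JSON truth
#'
#' The two channels are written as pages of one multi-page 16-bit TIFF
#' (intensities divided by 65535); the ground truth goes to a JSON sidecar
#' with 0-based (row, col) pixel coordinates.
#'
#' @param field Result of [generate_reporter_field()].
#' @param path Output TIFF path; the sidecar replaces the extension with
#'   `_truth.json`.
#' @return Named character vector of paths written, invisibly.
#' @export
write_reporter_field <- function(field, path) {
  tiff::writeTIFF(list(field$nuclei / 65535, field$reporter / 65535),
                  path, bits.per.sample = 16, compression = "none")
  truth_path <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  truth_path <- paste0(truth_path, "_truth.json")
  tr <- field$truth
  cells0 <- tr$cells; puncta0 <- tr$puncta
  cells0$row <- cells0$row - 1; cells0$col <- cells0$col - 1
  if (nrow(puncta0)) { puncta0$row <- puncta0$row - 1
                       puncta0$col <- puncta0$col - 1 }
  jsonlite::write_json(
    list(field_id = tr$field_id, pixel_size = tr$pixel_size, seed = tr$seed,
         coordinate_convention = "0-based (row, col)",
         cells = cells0, puncta = puncta0),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = path, truth = truth_path))
}

#' Read a multichannel reporter field TIFF
#'
#' Inverse of [write_reporter_field()] for the image part: returns the pages
#' of a multi-page TIFF as intensity matrices rescaled to 16-bit counts.
#'
#' @param path TIFF path.
#' @return List of numeric matrices, one per channel/page.
#' @export
read_reporter_field <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * 65535)
}
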