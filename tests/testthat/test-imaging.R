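test_that("nuclei segmentation finds isolated and touching nuclei", {
  # blank (noise-only) image: no labels
  set.seed(1)
  blank <- matrix(200 + rnorm(96 * 96, sd = 50), 96)
  expect_equal(max(segment_nuclei(blank)), 0)

  # well-separated synthetic nuclei are all recovered
  fld <- generate_reporter_field(12, image_shape = c(320, 320), seed = 4)
  labs <- segment_nuclei(fld$nuclei)
  expect_equal(max(labs), 12)
  st <- cmaquant:::label_stats(labs)
  for (i in seq_len(12)) {
    d <- sqrt((fld$truth$cells$row - st$row[i])^2 +
                (fld$truth$cells$col - st$col[i])^2)
    expect_lt(min(d), 2)  # centroids recovered to subpixel-ish accuracy
  }

  # constructed fixture: two touching nuclei split by watershed
  img <- matrix(100 + rnorm(64 * 64, sd = 3), 64)
  rows <- matrix(1:64, 64, 64); cols <- t(rows)
  img[(rows - 32)^2 + (cols - 26)^2 <= 49] <- 1100
  img[(rows - 32)^2 + (cols - 38)^2 <= 49] <- 1100
  labs2 <- segment_nuclei(img)
  expect_equal(max(labs2), 2)
  st2 <- cmaquant:::label_stats(labs2)
  expect_equal(sort(st2$col), c(26, 38), tolerance = 0.1)

  expect_error(segment_nuclei(array(0, c(4, 4, 2))), "2-D")
})

test_that("expressing-cell gate discounts reporter-negative cells", {
  fld <- generate_reporter_field(15, puncta_law = 2,
                                 expressing_fraction = 2 / 3, snr = 8,
                                 image_shape = c(384, 384), seed = 6)
  labs <- segment_nuclei(fld$nuclei)
  cells <- gate_expressing_cells(labs, fld$reporter)
  expect_equal(sum(cells$expressing), 10)   # 10 of 15 expressing
  tc <- fld$truth$cells
  for (i in seq_len(nrow(cells))) {
    j <- which.min((tc$row - cells$row[i])^2 + (tc$col - cells$col[i])^2)
    expect_equal(cells$expressing[i], tc$expressing[j])
  }

  # k = Inf gates out everything; empty label set is not an error
  expect_equal(sum(gate_expressing_cells(labs, fld$reporter,
                                         k = Inf)$expressing), 0)
  empty <- gate_expressing_cells(matrix(0L, 64, 64),
                                 matrix(200, 64, 64))
  expect_equal(nrow(empty), 0)
})

test_that("puncta counts are exact at SNR 8 and near-exact at SNR 5", {
  b8 <- puncta_benchmark(seeds = 1:3, snr = 8)
  expect_gte(b8$exact_fraction, 0.95)

  b5 <- puncta_benchmark(seeds = 4:6, snr = 5)
  expect_gte(b5$precision, 0.9)
  expect_gte(b5$recall, 0.9)
})

test_that("diffuse-only cells yield zero puncta", {
  fld <- generate_reporter_field(10, puncta_law = 0, snr = 8,
                                 image_shape = c(320, 320), seed = 8)
  res <- quantify_reporter_field(fld$nuclei, fld$reporter)
  expect_equal(res$n_expressing, 10)
  expect_equal(res$cells$puncta_count, rep(0L, 10))
})

test_that("counts and gating are invariant to multiplicative gain", {
  fld <- generate_reporter_field(10, puncta_law = 4, snr = 8,
                                 image_shape = c(320, 320), seed = 7)
  r1 <- quantify_reporter_field(fld$nuclei, fld$reporter)
  r2 <- quantify_reporter_field(fld$nuclei * 2, fld$reporter * 2)
  expect_identical(r1$cells$puncta_count, r2$cells$puncta_count)
  expect_identical(r1$cells$expressing, r2$cells$expressing)
  expect_identical(r1$cells$cma_positive, r2$cells$cma_positive)

  expect_error(detect_puncta(fld$reporter, data.frame()), "gate_expressing")
  cells <- gate_expressing_cells(segment_nuclei(fld$nuclei), fld$reporter)
  expect_error(detect_puncta(fld$reporter, cells, sigma = 20), "sigma")
  expect_error(detect_puncta(fld$reporter, cells, rel_threshold = 0.1),
               "rel_threshold")
})

test_that("CMA-positive classification uses the strict >3 rule", {
  # boundary: 3 puncta is negative, 4 is positive
  cls <- classify_cma_positive(c(3, 4))
  expect_equal(cls$positive, c(FALSE, TRUE))

  expect_equal(classify_cma_positive(c(0, 2, 4, 5, 3))$percent_positive, 40)
  expect_equal(classify_cma_positive(rep(0, 6))$percent_positive, 0)
  expect_error(classify_cma_positive(integer(0)), "empty")

  # raising the threshold never increases percent positive
  set.seed(2)
  counts <- rpois(40, 3)
  pct <- vapply(0:8, function(th)
    classify_cma_positive(counts, th)$percent_positive, numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("field QC keeps fields with at least 1/10 of the control cell count", {
  # control mean 100: a 10-cell field passes, a 9-cell field fails
  expect_equal(field_qc(c(10, 9), control_fields = c(100, 100)),
               c(TRUE, FALSE))
  # fraction 0: everything passes; identical fields always pass
  expect_true(all(field_qc(c(0, 3), c(50, 150), fraction = 0)))
  expect_true(all(field_qc(c(80, 80), c(80, 80))))
  expect_error(field_qc(c(10), numeric(0)), "empty control")

  # list-of-field-results interface sets qc_pass
  fr <- list(list(field_id = "a", n_nuclei = 10),
             list(field_id = "b", n_nuclei = 9))
  out <- field_qc(fr, list(list(n_nuclei = 100)))
  expect_true(out[[1]]$qc_pass)
  expect_false(out[[2]]$qc_pass)
})

test_that("tandem puncta split into dual and red-only by the green gate", {
  set.seed(3)
  red <- matrix(100 + rnorm(96 * 96, sd = 5), 96)
  green <- matrix(100 + rnorm(96 * 96, sd = 5), 96)
  pts <- expand.grid(row = c(20, 48, 76), col = c(20, 40, 60, 80))[1:10, ]
  dual_idx <- 1:6
  rows <- matrix(1:96, 96, 96); cols <- t(rows)
  for (j in seq_len(nrow(pts))) {
    disk <- (rows - pts$row[j])^2 + (cols - pts$col[j])^2 <= 9
    red[disk] <- 400
    if (j %in% dual_idx) green[disk] <- 400
  }
  res <- classify_tandem_puncta(red, green, pts)
  expect_equal(res$n_dual, 6)
  expect_equal(res$n_red_only, 4)
  expect_equal(res$n_dual + res$n_red_only, nrow(pts))
  expect_equal(res$flux_ratio, 0.4)
  expect_equal(which(res$per_punctum$dual), dual_idx)

  # all dual / none
  z <- classify_tandem_puncta(red, red, pts)
  expect_equal(z$n_dual, nrow(pts))
  none <- classify_tandem_puncta(red, green, pts[0, ])
  expect_equal(c(none$n_dual, none$n_red_only), c(0L, 0L))
  expect_true(is.na(none$flux_ratio))

  expect_error(classify_tandem_puncta(red, green[1:50, ], pts),
               "misaligned")
})
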