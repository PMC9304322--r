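test_that("expression generator is deterministic and honors the null design", {
  net <- default_cma_network()
  a <- generate_expression_dataset(net, 4, 4, seed = 42)
  b <- generate_expression_dataset(net, 4, 4, seed = 42)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$zmatrix$values, b$zmatrix$values)
  expect_false(identical(
    a$matrix$values,
    generate_expression_dataset(net, 4, 4, seed = 43)$matrix$values))

  # every network gene appears; groups labelled as constructed
  expect_true(all(net$gene_id %in% rownames(a$matrix$values)))
  expect_equal(as.vector(table(a$truth$group_labels)[c("control",
                                                       "treated")]),
               c(4L, 4L))

  # null design: per-gene treated-control difference within 3 SE of 0
  ds <- generate_expression_dataset(net, 50, 50, seed = 7)
  g <- ds$truth$group_labels[colnames(ds$zmatrix$values)]
  diff <- rowMeans(ds$zmatrix$values[, g == "treated"]) -
    rowMeans(ds$zmatrix$values[, g == "control"])
  se <- sqrt(2 / 50)
  expect_true(all(abs(diff) < 3 * se))

  expect_error(generate_expression_dataset(net, 1, 4), "at least 2")
  expect_error(generate_expression_dataset(net, 4, 4, noise_sd = -1),
               "positive")
})

test_that("programmed z-shifts land where stated", {
  net <- default_cma_network()
  eff <- c(LAMP2A = 1.5, RARA = -0.5)
  ds <- generate_expression_dataset(net, 100, 100, effects = eff, seed = 3)
  g <- ds$truth$group_labels[colnames(ds$zmatrix$values)]
  d <- rowMeans(ds$zmatrix$values[, g == "treated"]) -
    rowMeans(ds$zmatrix$values[, g == "control"])
  se3 <- 3 * sqrt(2 / 100)
  expect_lt(abs(d[["LAMP2A"]] - 1.5), se3)
  expect_lt(abs(d[["RARA"]] + 0.5), se3)
  expect_lt(abs(d[["HSPA8"]]), se3)
  # the raw log-scale matrix carries the same shift scaled by the noise SD
  expect_equal(ds$truth$gene_effects[["LAMP2A"]], 1.5)
})

test_that("expression dataset writes a matrix plus JSON truth sidecar", {
  net <- worked_network()
  ds <- generate_expression_dataset(net, 2, 2, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_expression_dataset(ds, dir)
  back <- read_expression_matrix(paths[["matrix"]], state = "log")
  expect_equal(back$values, ds$matrix$values)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 1)
  expect_equal(sort(names(truth$group_labels)),
               sort(colnames(ds$matrix$values)))
})

test_that("reporter field generator keeps exhaustive, reconciled truth", {
  # bookkeeping: 50 cells at 4 puncta each -> 50 cells, 200 puncta listed
  fld <- generate_reporter_field(50, puncta_law = 4,
                                 image_shape = c(640, 640), seed = 2)
  expect_equal(nrow(fld$truth$cells), 50)
  expect_equal(nrow(fld$truth$puncta), 200)
  expect_equal(sum(fld$truth$cells$n_puncta), 200)
  expect_equal(unname(table(fld$truth$puncta$cell_id)),
               rep(4L, 50), ignore_attr = TRUE)

  # puncta lie inside their cell's cytosol annulus
  ctr <- fld$truth$cells[fld$truth$puncta$cell_id, ]
  d <- sqrt((fld$truth$puncta$row - ctr$row)^2 +
              (fld$truth$puncta$col - ctr$col)^2)
  expect_true(all(d > fld$truth$nucleus_radius))
  expect_true(all(d < fld$truth$nucleus_radius + fld$truth$cyto_width))

  # empty field: blank truth, channels at background
  f0 <- generate_reporter_field(0, seed = 1)
  expect_equal(nrow(f0$truth$cells), 0)
  expect_equal(nrow(f0$truth$puncta), 0)
  expect_lt(abs(mean(f0$nuclei) - 200), 5)

  expect_error(generate_reporter_field(100, image_shape = c(128, 128),
                                       seed = 1),
               "infeasible packing")
  expect_error(generate_reporter_field(5, snr = 0), "snr")
})

test_that("identical seeds give bit-identical TIFF files", {
  f1 <- generate_reporter_field(5, seed = 11)
  f2 <- generate_reporter_field(5, seed = 11)
  t1 <- withr::local_tempfile(fileext = ".tif")
  t2 <- withr::local_tempfile(fileext = ".tif")
  write_reporter_field(f1, t1)
  write_reporter_field(f2, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))

  # truth sidecar uses 0-based coordinates
  truth <- jsonlite::read_json(sub("\\.tif$", "_truth.json", t1),
                               simplifyVector = TRUE)
  expect_equal(truth$cells$row, f1$truth$cells$row - 1)

  # 16-bit quantization round-trips to within one grey level
  ch <- read_reporter_field(t1)
  expect_lt(max(abs(ch[[2]] - f1$reporter)), 1.01)
})

test_that("binding-curve generator follows the stated titration protocol", {
  bc <- generate_binding_curve(ec50 = 1, noise_sd_mP = 0)
  # two-fold series from 10 uM: lowest concentration 10 / 2^11
  expect_equal(nrow(bc), 12)
  expect_equal(max(bc$conc_uM), 10)
  expect_equal(min(bc$conc_uM), 10 / 2^11)
  expect_equal(attr(bc, "probe_nM"), 5)  # probe default
  expect_true(all(diff(bc$conc_uM) > 0))

  # curve value at the EC50 is the plateau midpoint
  mid <- (50 + 250) / 2
  at_ec50 <- 50 + (250 - 50) * 1 / (1 + 1)
  expect_equal(at_ec50, mid)
  # interpolating the generated noiseless curve at 1 uM hits the midpoint
  f <- approxfun(log(bc$conc_uM), bc$mP)
  expect_equal(f(log(1)), mid, tolerance = 0.02)

  expect_identical(generate_binding_curve(seed = 4, noise_sd_mP = 3),
                   generate_binding_curve(seed = 4, noise_sd_mP = 3))
  expect_error(generate_binding_curve(ec50 = -1), "ec50")
  expect_error(generate_binding_curve(n_points = 3), "at least 4")
})

test_that("PK profile generator obeys half-life and model nesting", {
  pk <- generate_pk_profile(times = c(1, 2, 4),
                            params = list(C1 = 100, k1 = log(2) / 2))
  expect_equal(pk$conc[pk$time_h == 2], 50)  # one half-life from C0 = 100

  expect_identical(
    generate_pk_profile(times = c(1, 2, 4), noise_cv = 0.3, seed = 9),
    generate_pk_profile(times = c(1, 2, 4), noise_cv = 0.3, seed = 9))

  # bi-exponential with zero second coefficient equals the mono-exponential
  mono <- generate_pk_profile(times = c(0.5, 1, 2, 8), model = "mono",
                              params = list(C1 = 80, k1 = 0.4))
  bi <- generate_pk_profile(times = c(0.5, 1, 2, 8), model = "bi",
                            params = list(C1 = 80, k1 = 0.4, C2 = 0,
                                          k2 = 2))
  expect_equal(bi$conc, mono$conc)

  expect_true(all(generate_pk_profile(times = c(1, 2, 4), noise_cv = 1,
                                      seed = 2)$conc >= 0))
  expect_error(generate_pk_profile(times = numeric(0)), "empty time grid")
  expect_error(generate_pk_profile(times = c(2, 1, 3)),
               "strictly increasing")
})
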