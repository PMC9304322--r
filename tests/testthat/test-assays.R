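test_that("EC50 fits recover noiseless and noisy curves", {
  bc <- generate_binding_curve(ec50 = 1, noise_sd_mP = 0)
  fit <- fit_binding_ec50(bc)
  expect_lt(abs(fit$ec50 - 1) / 1, 1e-6)
  expect_equal(fit$bottom, 50, tolerance = 1e-6)
  expect_equal(fit$top, 250, tolerance = 1e-6)
  expect_false(fit$extrapolated)
  expect_false(fit$unreliable)

  # depletion model on depletion-generated data, EC50 = Kd + probe/2
  bcd <- generate_binding_curve(ec50 = 0.05, noise_sd_mP = 0,
                                model = "depletion")
  fd <- fit_binding_ec50(bcd, model = "one_site_depletion")
  expect_lt(abs(fd$ec50 - 0.05) / 0.05, 1e-5)
  expect_equal(fd$kd, 0.05 - 0.0025, tolerance = 1e-4)

  # median relative error under 2 mP noise stays below 10%
  errs <- vapply(1:60, function(s) {
    f <- fit_binding_ec50(generate_binding_curve(ec50 = 1, noise_sd_mP = 2,
                                                 seed = s))
    abs(f$ec50 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("EC50 is invariant to affine transforms of the polarization axis", {
  bc <- generate_binding_curve(ec50 = 0.7, noise_sd_mP = 1, seed = 5)
  f0 <- fit_binding_ec50(bc)
  bc2 <- bc
  bc2$mP <- 3.1 * bc2$mP + 40
  f2 <- fit_binding_ec50(bc2)
  expect_equal(f2$ec50, f0$ec50, tolerance = 1e-6)
})

test_that("paired curves recover a programmed EC50 ratio", {
  # ligand stabilization: EC50 2.0 vs 0.5 uM -> ratio 4
  fits <- lapply(c(2.0, 0.5), function(e)
    fit_binding_ec50(generate_binding_curve(ec50 = e, noise_sd_mP = 1,
                                            seed = 21)))
  ratio <- fits[[1]]$ec50 / fits[[2]]$ec50
  expect_equal(ratio, 4, tolerance = 0.15)
  # and the truth ratio lies inside the combined confidence band
  expect_true(fits[[1]]$ci[1] / fits[[2]]$ci[2] <= 4)
  expect_true(fits[[1]]$ci[2] / fits[[2]]$ci[1] >= 4)
})

test_that("flat curves are flagged unreliable", {
  bc <- generate_binding_curve(ec50 = 1, noise_sd_mP = 0)
  set.seed(2)
  bc$mP <- 150 + rnorm(nrow(bc), 0, 3)  # pure noise, no transition
  f <- fit_binding_ec50(bc)
  expect_true(f$unreliable || f$extrapolated)
})

test_that("NCA reproduces closed-form mono-exponential parameters", {
  pk <- generate_pk_profile(times = c(0.25, 0.5, 1, 2, 4, 8, 24),
                            params = list(C1 = 100, k1 = log(2) / 2))
  res <- nca_parameters(pk)
  expect_equal(res$t_half, 2)
  expect_equal(res$cmax, 100 * 2^(-0.25 / 2))
  expect_equal(res$tmax, 0.25)
  expect_gte(res$auc_inf, res$auc_last)

  # dense grid: trapezoid AUC within 2% of the analytic 100 * 2 / ln 2
  dense <- generate_pk_profile(times = seq(0.01, 60, by = 0.01),
                               params = list(C1 = 100, k1 = log(2) / 2))
  auc <- nca_parameters(dense, terminal_points = 5)$auc_inf
  expect_lt(abs(auc - 200 / log(2)) / (200 / log(2)), 0.02)

  # trapezoid error shrinks as the grid refines
  errs <- vapply(c(2, 1, 0.25), function(dt) {
    p <- generate_pk_profile(times = seq(dt, 24, by = dt),
                             params = list(C1 = 100, k1 = log(2) / 2))
    abs(nca_parameters(p)$auc_last -
          (200 / log(2)) * (2^(-dt / 2) - 2^(-12)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("NCA handles absorption peaks and flat terminal phases", {
  # oral-type profile peaking at t = 1
  po <- data.frame(time_h = c(0.25, 0.5, 1, 2, 4, 8),
                   conc = c(20, 60, 90, 70, 35, 10))
  res <- nca_parameters(po)
  expect_equal(res$tmax, 1)
  expect_equal(res$cmax, 90)

  # rising terminal phase: half-life undefined, flagged
  bad <- data.frame(time_h = 1:4, conc = c(10, 9, 11, 12))
  rb <- nca_parameters(bad)
  expect_true(is.na(rb$t_half))
  expect_match(rb$flags, "half-life undefined", all = FALSE)

  expect_error(nca_parameters(data.frame(time_h = c(1, 1, 2),
                                         conc = c(1, 2, 3))),
               "strictly increasing")
})

test_that("matrix ratios compare like with like", {
  brain <- generate_pk_profile(times = c(0.5, 1, 2, 4, 8),
                               params = list(C1 = 300, k1 = 0.2),
                               matrix = "brain")
  plasma <- generate_pk_profile(times = c(0.5, 1, 2, 4, 8),
                                params = list(C1 = 60, k1 = 0.2))
  rb <- nca_parameters(brain); rp <- nca_parameters(plasma)
  # same shape scaled 5x: AUC and Cmax ratios are both exactly 5
  expect_equal(matrix_ratio(rb, rp, "AUC"), 5)
  expect_equal(matrix_ratio(rb, rp, "Cmax"), 5)

  po <- generate_pk_profile(times = c(0.5, 1, 2, 4, 8),
                            params = list(C1 = 60, k1 = 0.2), route = "PO")
  expect_error(matrix_ratio(rb, nca_parameters(po)), "route mismatch")
})

test_that("unit conversion is dimensionally exact and invertible", {
  expect_equal(ng_per_g_to_micromolar(500, 500), 1)
  expect_equal(ng_per_g_to_micromolar(0, 450.5), 0)
  expect_error(ng_per_g_to_micromolar(100, 0), "molecular_weight")

  # round trip at several MWs and densities
  for (mw in c(350.4, 450.5, 612)) {
    for (dens in c(1, 1.04)) {
      x <- 123.456
      expect_equal(
        ng_per_g_to_micromolar(micromolar_to_ng_per_g(x, mw, dens), mw,
                               dens),
        x, tolerance = 1e-12)
    }
  }
})

test_that("proteolysis percentages and inhibitor-sensitive shares", {
  rec <- data.frame(time_h = c(4, 8, 8), soluble_dpm = c(200, 800, 0),
                    precipitable_dpm = c(800, 200, 500),
                    condition = c("none", "none", "lysosomal"))
  pp <- percent_proteolysis(rec)
  expect_equal(pp$percent, c(20, 80, 0))
  expect_equal(percent_proteolysis(rec, t = 4)$percent, 20)
  expect_error(percent_proteolysis(
    data.frame(time_h = 1, soluble_dpm = 0, precipitable_dpm = 0)),
    "zero")

  # total 30% vs 20% with the macroautophagy inhibitor: 10 points, 1/3
  pf <- pathway_fraction(30, 20)
  expect_equal(pf$points, 10)
  expect_equal(pf$share, 1 / 3)
  expect_false(pf$flagged_negative)

  expect_equal(pathway_fraction(30, 30)$points, 0)  # no inhibitor effect
  expect_true(pathway_fraction(20, 30)$flagged_negative)
  expect_error(pathway_fraction(0, 10), "total")
  expect_error(pathway_fraction(120, 10), "\\[0, 100\\]")
})
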