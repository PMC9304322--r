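#' Simulate a fluorescence-polarization receptor titration
#'
#' Generates a direct-binding isotherm as acquired in FP assays: a
#' fluorescent probe (default 5 nM, emulating a FITC-labelled co-repressor
#' peptide) titrated with receptor concentrations forming a geometric
#' dilution series from `top_conc` (default 10 uM, two-fold steps).
#' Polarization follows either the one-site hyperbolic law
#' `mP = bottom + (top - bottom) * C / (C + EC50)` or, with
#' `model = "depletion"`, the quadratic equilibrium that accounts for probe
#' depletion (then `Kd = EC50 - probe/2000` uM). Gaussian noise of SD
#' `noise_sd_mP` is added.
#'
#' @param ec50 Half-maximal receptor concentration in uM; must be > 0.
#' @param top_conc Highest receptor concentration in uM (default 10).
#' @param dilution_factor Fold-dilution per step, > 1 (default 2).
#' @param n_points Number of concentrations, at least 4 (default 12).
#' @param probe_nM Probe concentration in nM (default 5).
#' @param noise_sd_mP Gaussian noise SD in mP units, >= 0 (default 0).
#' @param seed Integer seed.
#' @param bottom_mP,top_mP Free and fully-bound polarization plateaus.
#' @param model `"hyperbolic"` (default) or `"depletion"`.
#' @return Data frame with columns `conc_uM` (ascending) and `mP`;
#'   attributes `probe_nM` and `truth` (generation parameters).
#' @examples
#' bc <- generate_binding_curve(ec50 = 1, noise_sd_mP = 0)
#' range(bc$conc_uM)  # 10 / 2^11 ... 10
#' @export
generate_binding_curve <- function(ec50 = 1, top_conc = 10,
                                   dilution_factor = 2, n_points = 12,
                                   probe_nM = 5, noise_sd_mP = 0, seed = 1,
                                   bottom_mP = 50, top_mP = 250,
                                   model = c("hyperbolic", "depletion")) {
  model <- match.arg(model)
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (top_conc <= 0) stop("top_conc must be > 0")
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (n_points < 4) stop("need at least 4 concentration points")
  if (noise_sd_mP < 0) stop("noise_sd_mP must be >= 0")

  conc <- top_conc / dilution_factor^(seq_len(n_points) - 1)
  conc <- sort(conc)
  probe_uM <- probe_nM / 1000
  fb <- switch(model,
    hyperbolic = conc / (conc + ec50),
    depletion = {
      kd <- ec50 - probe_uM / 2
      if (kd <= 0) stop("ec50 too small for the probe concentration ",
                        "(Kd = ec50 - probe/2 must be > 0)")
      b <- conc + probe_uM + kd
      ((b - sqrt(b^2 - 4 * conc * probe_uM)) / (2 * probe_uM))
    })
  mP <- bottom_mP + (top_mP - bottom_mP) * fb
  if (noise_sd_mP > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    mP <- mP + stats::rnorm(n_points, 0, noise_sd_mP)
  }
  out <- data.frame(conc_uM = conc, mP = mP)
  attr(out, "probe_nM") <- probe_nM
  attr(out, "truth") <- list(ec50 = ec50, bottom_mP = bottom_mP,
                             top_mP = top_mP, model = model,
                             noise_sd_mP = noise_sd_mP, seed = seed)
  out
}

#' Simulate a concentration-time pharmacokinetic profile
#'
#' Generates mono- or bi-exponential concentration-time data emulating a
#' sparse in-vivo sampling grid:
#' `C(t) = C1 exp(-k1 t) + C2 exp(-k2 t)` with multiplicative log-normal
#' noise of coefficient of variation `noise_cv` (concentrations therefore
#' stay non-negative). A bi-exponential with `C2 = 0` reduces exactly to the
#' mono-exponential.
#'
#' @param dose Dose in mg/kg, recorded in attributes.
#' @param model `"mono"` or `"bi"`.
#' @param params Named list of coefficients and rate constants: `C1`, `k1`
#'   and for `"bi"` also `C2`, `k2`. Concentrations in ng/mL (plasma) or
#'   ng/g (tissue); rate constants in 1/h.
#' @param times Strictly increasing sampling times in hours, at least 3.
#' @param noise_cv Log-normal noise CV, >= 0 (default 0).
#' @param seed Integer seed.
#' @param matrix Sampled matrix, `"plasma"` or `"brain"`.
#' @param route Administration route, `"IV"` or `"PO"`.
#' @return Data frame `time_h`, `conc`; attributes `dose`, `matrix`,
#'   `route`, `truth`.
#' @examples
#' pk <- generate_pk_profile(times = c(0.25, 0.5, 1, 2, 4, 8),
#'                           params = list(C1 = 100, k1 = log(2) / 2))
#' pk$conc[pk$time_h == 2]  # 50: one half-life
#' @export
generate_pk_profile <- function(dose = 1, model = c("mono", "bi"),
                                params = list(C1 = 100, k1 = log(2) / 2),
                                times = c(0.25, 0.5, 1, 2, 4, 8, 24),
                                noise_cv = 0, seed = 1,
                                matrix = c("plasma", "brain"),
                                route = c("IV", "PO")) {
  model <- match.arg(model)
  matrix <- match.arg(matrix)
  route <- match.arg(route)
  if (!length(times)) stop("empty time grid")
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  C1 <- params$C1; k1 <- params$k1
  if (is.null(C1) || is.null(k1)) stop("params must contain C1 and k1")
  conc <- C1 * exp(-k1 * times)
  if (model == "bi") {
    C2 <- params$C2 %||% 0
    k2 <- params$k2 %||% k1
    conc <- conc + C2 * exp(-k2 * times)
  }
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog))
  }
  out <- data.frame(time_h = times, conc = conc)
  attr(out, "dose") <- dose
  attr(out, "matrix") <- matrix
  attr(out, "route") <- route
  attr(out, "truth") <- list(model = model, params = params,
                             noise_cv = noise_cv, seed = seed)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
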