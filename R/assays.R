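#' Fit an EC50 to a fluorescence-polarization binding isotherm
#'
#' Fits a receptor-titration polarization curve by nonlinear least squares
#' and reports the EC50 (receptor concentration at half-maximal polarization
#' change). Two models are offered:
#' \describe{
#'   \item{`"logistic"`}{Four-parameter logistic on log10 concentration,
#'     `mP = bottom + (top - bottom) / (1 + 10^(hill (log10 EC50 - log10 C)))`.
#'     With `hill = 1` this is exactly the one-site hyperbola.}
#'   \item{`"one_site_depletion"`}{One-site binding solving the quadratic
#'     equilibrium for probe fraction bound, accounting for the finite probe
#'     concentration (relevant when probe and receptor are commensurate at
#'     the curve foot); then `EC50 = Kd + probe/2`.}
#' }
#' The confidence interval is Wald-type on the log10 EC50 (or log10 Kd)
#' scale. The fit is flagged `extrapolated` when the EC50 falls outside the
#' tested concentration range and `unreliable` when no transition is
#' resolved (fitted dynamic range under 3 residual SDs) or the optimizer
#' fails.
#'
#' @param curve Data frame with columns `conc_uM` (strictly positive) and
#'   `mP`, e.g. from [generate_binding_curve()]; at least 5 points.
#' @param model `"logistic"` (default) or `"one_site_depletion"`.
#' @param probe_nM Probe concentration in nM for the depletion model;
#'   defaults to the curve's `probe_nM` attribute, else 5.
#' @param fix_hill Fix the logistic Hill slope at 1 (default `TRUE`, the
#'   one-site reading); `FALSE` frees it.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `binding_fit` list: `ec50`, `ci` (lower, upper), `bottom`,
#'   `top`, `hill`, `kd` (depletion model), `model`, `residual_sd`,
#'   `extrapolated`, `unreliable`, `fit` (the `nls` object or `NULL`).
#' @examples
#' bc <- generate_binding_curve(ec50 = 1, noise_sd_mP = 0)
#' fit_binding_ec50(bc)$ec50  # 1
#' @export
fit_binding_ec50 <- function(curve, model = c("logistic",
                                              "one_site_depletion"),
                             probe_nM = NULL, fix_hill = TRUE,
                             conf_level = 0.95) {
  model <- match.arg(model)
  if (!all(c("conc_uM", "mP") %in% names(curve)))
    stop("curve needs columns 'conc_uM' and 'mP'")
  if (nrow(curve) < 5) stop("need at least 5 points")
  if (any(curve$conc_uM <= 0)) stop("concentrations must be > 0")
  if (is.null(probe_nM))
    probe_nM <- attr(curve, "probe_nM") %||% 5
  conc <- curve$conc_uM
  y <- curve$mP
  lo <- min(y); hi <- max(y)
  mid <- (lo + hi) / 2
  start_log_ec50 <- log10(conc[which.min(abs(y - mid))])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  fit <- NULL
  unreliable <- FALSE
  if (model == "logistic") {
    form <- if (fix_hill)
      mP ~ bottom + (top - bottom) / (1 + 10^(lec50 - log10(conc_uM)))
    else
      mP ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 -
                                                        log10(conc_uM))))
    start <- list(bottom = lo, top = hi, lec50 = start_log_ec50)
    if (!fix_hill) start$hill <- 1
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = curve, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(ec50 = NA_real_, ci = c(NA_real_, NA_real_),
                            bottom = NA_real_, top = NA_real_,
                            hill = NA_real_, kd = NA_real_, model = model,
                            residual_sd = NA_real_, extrapolated = NA,
                            unreliable = TRUE, fit = NULL),
                       class = "binding_fit"))
    }
    cf <- stats::coef(fit)
    ec50 <- 10^cf[["lec50"]]
    kd <- NA_real_
    hill <- if (fix_hill) 1 else cf[["hill"]]
    se <- sqrt(diag(stats::vcov(fit)))[["lec50"]]
    ci <- 10^(cf[["lec50"]] + c(-1, 1) * z * se)
  } else {
    probe_uM <- probe_nM / 1000
    frac_bound <- function(conc_uM, kd) {
      b <- conc_uM + probe_uM + kd
      (b - sqrt(b^2 - 4 * conc_uM * probe_uM)) / (2 * probe_uM)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mP ~ bottom + (top - bottom) * frac_bound(conc_uM, 10^lkd),
        data = curve,
        start = list(bottom = lo, top = hi, lkd = start_log_ec50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(ec50 = NA_real_, ci = c(NA_real_, NA_real_),
                            bottom = NA_real_, top = NA_real_,
                            hill = NA_real_, kd = NA_real_, model = model,
                            residual_sd = NA_real_, extrapolated = NA,
                            unreliable = TRUE, fit = NULL),
                       class = "binding_fit"))
    }
    cf <- stats::coef(fit)
    kd <- 10^cf[["lkd"]]
    ec50 <- kd + probe_uM / 2
    hill <- NA_real_
    se <- sqrt(diag(stats::vcov(fit)))[["lkd"]]
    ci <- 10^(cf[["lkd"]] + c(-1, 1) * z * se) + probe_uM / 2
  }
  rsd <- sqrt(sum(stats::residuals(fit)^2) /
                max(1, nrow(curve) - length(stats::coef(fit))))
  span <- abs(cf[["top"]] - cf[["bottom"]])
  if (span < 3 * rsd) unreliable <- TRUE
  structure(list(ec50 = unname(ec50), ci = unname(ci),
                 bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
                 hill = unname(hill), kd = unname(kd), model = model,
                 residual_sd = rsd,
                 extrapolated = ec50 < min(conc) || ec50 > max(conc),
                 unreliable = unreliable, fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("EC50 = %.4g uM [%.4g, %.4g] (%s)%s%s\n",
              x$ec50, x$ci[1], x$ci[2], x$model,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else "",
              if (isTRUE(x$unreliable)) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Non-compartmental pharmacokinetic parameters
#'
#' Standard NCA summary of a concentration-time profile: `Cmax` and `Tmax`
#' by inspection, `AUC_last` by the linear trapezoidal rule over the
#' observed points, terminal slope by least squares on log concentration
#' over the last `terminal_points` positive observations,
#' `t1/2 = ln 2 / lambda_z`, and
#' `AUC_inf = AUC_last + C_last / lambda_z`. A non-negative terminal slope
#' leaves the half-life undefined (`NA`, flagged).
#'
#' @param profile Data frame with columns `time_h` (strictly increasing)
#'   and `conc`, e.g. from [generate_pk_profile()]; at least 3 positive
#'   concentrations.
#' @param terminal_points Number of terminal points for the log-linear
#'   regression, at least 3 (default 3).
#' @return A `pk_result` list: `cmax`, `tmax`, `auc_last`, `auc_inf`,
#'   `t_half`, `lambda_z`, `n_terminal`, `flags` (character vector),
#'   `matrix`, `route`, `dose` (carried from the profile's attributes).
#' @examples
#' pk <- generate_pk_profile(times = c(0.5, 1, 2, 4, 8),
#'                           params = list(C1 = 100, k1 = log(2) / 2))
#' nca_parameters(pk)$t_half  # 2
#' @export
nca_parameters <- function(profile, terminal_points = 3) {
  if (!all(c("time_h", "conc") %in% names(profile)))
    stop("profile needs columns 'time_h' and 'conc'")
  if (terminal_points < 3) stop("terminal_points must be at least 3")
  t <- profile$time_h
  conc <- profile$conc
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (sum(conc > 0) < 3) stop("need at least 3 positive concentrations")
  cmax <- max(conc)
  tmax <- t[which.max(conc)]
  auc_last <- sum(diff(t) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)

  pos <- which(conc > 0)
  term <- utils::tail(pos, terminal_points)
  flags <- character(0)
  if (length(term) < terminal_points)
    flags <- c(flags, "fewer positive points than requested terminal_points")
  fit <- stats::lm(log(conc[term]) ~ t[term])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    flags <- c(flags, "non-declining terminal phase; half-life undefined")
    lambda_z <- NA_real_
    t_half <- NA_real_
    auc_inf <- NA_real_
  } else {
    lambda_z <- -slope
    t_half <- log(2) / lambda_z
    auc_inf <- auc_last + conc[length(conc)] / lambda_z
  }
  structure(list(cmax = cmax, tmax = tmax, auc_last = auc_last,
                 auc_inf = auc_inf, t_half = t_half, lambda_z = lambda_z,
                 n_terminal = length(term), flags = flags,
                 matrix = attr(profile, "matrix"),
                 route = attr(profile, "route"),
                 dose = attr(profile, "dose")),
            class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  cat(sprintf(
    "NCA: Cmax %.4g @ Tmax %.3g h | AUC_last %.4g | AUC_inf %.4g | t1/2 %.3g h\n",
    x$cmax, x$tmax, x$auc_last, x$auc_inf, x$t_half))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tissue-to-plasma exposure ratio
#'
#' Ratio of a chosen NCA metric between two matrices (e.g. brain over
#' plasma) for the same compound, dose and route.
#'
#' @param result_a,result_b `pk_result` objects (numerator, denominator).
#' @param metric `"AUC"` (uses `auc_last`) or `"Cmax"`.
#' @return The ratio (a single number).
#' @examples
#' \dontrun{matrix_ratio(brain_nca, plasma_nca, "AUC")}
#' @export
matrix_ratio <- function(result_a, result_b, metric = c("AUC", "Cmax")) {
  metric <- match.arg(metric)
  for (r in list(result_a, result_b))
    if (!inherits(r, "pk_result")) stop("inputs must be pk_result objects")
  if (!is.null(result_a$route) && !is.null(result_b$route) &&
      !identical(result_a$route, result_b$route))
    stop("route mismatch: ", result_a$route, " vs ", result_b$route)
  if (!is.null(result_a$dose) && !is.null(result_b$dose) &&
      !identical(result_a$dose, result_b$dose))
    stop("dose mismatch: ", result_a$dose, " vs ", result_b$dose)
  num <- if (metric == "AUC") result_a$auc_last else result_a$cmax
  den <- if (metric == "AUC") result_b$auc_last else result_b$cmax
  if (!is.finite(den) || den == 0) stop("zero or undefined denominator")
  num / den
}

#' Convert a tissue concentration from ng/g to micromolar
#'
#' `uM = conc[ng/g] * density[g/mL] / MW[g/mol]`: 1 ng/g of tissue at unit
#' density is 1 ng/mL = 1 ug/L, and dividing by the molecular weight in
#' g/mol (= ug/umol) yields umol/L. Used to compare measured tissue Cmax
#' and AUC-derived levels with effective in-vitro concentrations.
#'
#' @param conc Concentration in ng/g (or ng/mL for fluids), >= 0.
#' @param molecular_weight Compound molecular weight in g/mol, > 0.
#' @param tissue_density Tissue density in g/mL (default 1).
#' @return Concentration in uM.
#' @examples
#' ng_per_g_to_micromolar(500, 500)  # 1
#' @export
ng_per_g_to_micromolar <- function(conc, molecular_weight,
                                   tissue_density = 1) {
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  if (tissue_density <= 0) stop("tissue_density must be > 0")
  conc * tissue_density / molecular_weight
}

#' Convert a micromolar concentration back to ng/g
#'
#' Inverse of [ng_per_g_to_micromolar()].
#'
#' @inheritParams ng_per_g_to_micromolar
#' @param conc_uM Concentration in uM.
#' @return Concentration in ng/g.
#' @export
micromolar_to_ng_per_g <- function(conc_uM, molecular_weight,
                                   tissue_density = 1) {
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  if (tissue_density <= 0) stop("tissue_density must be > 0")
  conc_uM * molecular_weight / tissue_density
}

#' Percent proteolysis from radiolabel partitioning
#'
#' In a pulse-chase proteolysis assay, degradation at time `t` is the
#' fraction of radioactivity converted from acid-precipitable (intact
#' protein) to acid-soluble (degraded) form:
#' `100 * soluble / (soluble + precipitable)`.
#'
#' @param record Data frame with columns `time_h`, `soluble_dpm`,
#'   `precipitable_dpm` (dpm >= 0), optionally `condition`.
#' @param t Time point present in `record$time_h`; when `NULL` (default)
#'   all time points are returned.
#' @return Data frame `time_h`, `percent` (plus `condition` if present).
#' @examples
#' rec <- data.frame(time_h = c(4, 8), soluble_dpm = c(200, 800),
#'                   precipitable_dpm = c(800, 200))
#' percent_proteolysis(rec)$percent  # 20 80
#' @export
percent_proteolysis <- function(record, t = NULL) {
  req <- c("time_h", "soluble_dpm", "precipitable_dpm")
  missing_cols <- setdiff(req, names(record))
  if (length(missing_cols))
    stop("record is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(record$soluble_dpm < 0) || any(record$precipitable_dpm < 0))
    stop("dpm values must be >= 0")
  if (!is.null(t)) {
    record <- record[record$time_h %in% t, , drop = FALSE]
    if (!nrow(record)) stop("time point(s) not found in record")
  }
  tot <- record$soluble_dpm + record$precipitable_dpm
  if (any(tot == 0))
    stop("soluble + precipitable is zero at time(s): ",
         paste(record$time_h[tot == 0], collapse = ", "))
  out <- data.frame(time_h = record$time_h,
                    percent = 100 * record$soluble_dpm / tot)
  if ("condition" %in% names(record)) out$condition <- record$condition
  rownames(out) <- NULL
  out
}

#' Inhibitor-sensitive share of proteolysis
#'
#' Decomposes total degradation into the fraction blocked by an inhibitor
#' (e.g. lysosomal inhibitors for lysosomal degradation, an ULK1/2
#' inhibitor for macroautophagy): the sensitive component is
#' `total - with_inhibitor` percentage points, and its share of total is
#' `sensitive / total`. A negative difference (inhibitor apparently
#' increasing degradation) is flagged, not clamped.
#'
#' @param total Percent proteolysis without inhibitor, in \[0, 100\].
#' @param with_inhibitor Percent proteolysis with inhibitor, in \[0, 100\].
#' @return List: `points` (percentage points), `share` (fraction of total),
#'   `flagged_negative`.
#' @examples
#' pathway_fraction(30, 20)  # 10 points, share 1/3
#' @export
pathway_fraction <- function(total, with_inhibitor) {
  for (v in c(total, with_inhibitor))
    if (!is.finite(v) || v < 0 || v > 100)
      stop("percentages must lie in [0, 100]")
  if (total == 0 && with_inhibitor > 0)
    stop("total proteolysis is 0 but inhibitor value is positive")
  points <- total - with_inhibitor
  list(points = points,
       share = if (total > 0) points / total else 0,
       flagged_negative = points < 0)
}
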