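# Quantitative biochemistry for the coupled-assay and metabolite work:
# Michaelis-Menten fitting (double-reciprocal and nonlinear), standard-
# addition quantification with first-order error propagation, LOD/LOQ
# under the 3-sigma / 10-sigma convention, and an equimolar-product
# stoichiometry check.

#' Construct a kinetic dataset
#'
#' @param substrate Substrate concentrations (mM), all > 0.
#' @param rate Initial velocities (arbitrary units per min), same length.
#' @param replicate Optional replicate identifiers.
#' @return A `kinetic_dataset`.
#' @export
kinetic_dataset <- function(substrate, rate, replicate = NULL) {
  stopifnot(length(substrate) == length(rate))
  if (any(substrate <= 0)) stop("substrate concentrations must be > 0")
  if (length(unique(substrate)) < 3) {
    stop("need at least 3 distinct substrate concentrations for fitting")
  }
  structure(list(substrate = as.numeric(substrate), rate = as.numeric(rate),
                 replicate = replicate %||% rep(1L, length(rate))),
            class = "kinetic_dataset")
}

#' Fit Michaelis-Menten kinetics
#'
#' `method = "double_reciprocal"` performs the classical Lineweaver-Burk
#' fit: ordinary least squares of 1/v on 1/S, with `Km = slope/intercept`
#' and `Vmax = 1/intercept`. The reciprocal transform makes the noise
#' heteroscedastic, so a warning notes the caveat and a direct nonlinear
#' least-squares fit of `v = Vmax*S/(Km+S)` (initialized from the
#' reciprocal estimates) is co-reported whenever it converges.
#' `method = "nonlinear"` makes the nonlinear fit primary.
#'
#' Standard errors for the reciprocal method come from first-order
#' propagation of the OLS coefficient covariance.
#'
#' @param data A [kinetic_dataset()].
#' @param method `"double_reciprocal"` or `"nonlinear"`.
#' @return A `kinetic_fit`: `km` (mM), `vmax`, `km_se`, `vmax_se`,
#'   `r_squared`, `method`, `flags`, and `alternative` (the co-reported
#'   fit, or `NULL`).
#' @export
fit_michaelis_menten <- function(data,
                                 method = c("double_reciprocal", "nonlinear")) {
  stopifnot(inherits(data, "kinetic_dataset"))
  method <- match.arg(method)
  primary <- switch(method,
                    double_reciprocal = fit_mm_reciprocal(data),
                    nonlinear = fit_mm_nls(data))
  alt <- switch(method,
                double_reciprocal = tryCatch(
                  fit_mm_nls(data, init = primary), error = function(e) NULL),
                nonlinear = tryCatch(
                  suppressWarnings(fit_mm_reciprocal(data)),
                  error = function(e) NULL))
  primary$alternative <- alt
  primary
}

fit_mm_reciprocal <- function(data) {
  S <- data$substrate; v <- data$rate
  if (any(v <= 0)) {
    stop("method error: nonpositive rate is incompatible with the ",
         "double-reciprocal transform; use method = \"nonlinear\"")
  }
  warning("double-reciprocal (Lineweaver-Burk) fitting weights low-rate ",
          "points heavily; the nonlinear fit is co-reported", call. = FALSE)
  fit <- lm(I(1 / v) ~ I(1 / S))
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  V <- suppressWarnings(vcov(fit))   # summary.lm warns on perfect fits
  flags <- character(0)
  if (b0 <= 0) flags <- c(flags, "fit_failure:nonpositive_intercept")
  if (abs(b1) < 1e-12 * max(abs(b0), 1)) flags <- c(flags, "km_zero:zero_order_regime")
  km <- b1 / b0
  vmax <- 1 / b0
  # delta method: g1 = Km = b1/b0, g2 = Vmax = 1/b0
  km_se <- sqrt(max(0, V[2, 2] / b0^2 + b1^2 * V[1, 1] / b0^4 -
                      2 * b1 * V[1, 2] / b0^3))
  vmax_se <- sqrt(max(0, V[1, 1] / b0^4))
  new_kinetic_fit(km, vmax, km_se, vmax_se,
                  r_squared = suppressWarnings(summary(fit))$r.squared,
                  method = "double_reciprocal", flags = flags,
                  coef = c(intercept = b0, slope = b1))
}

fit_mm_nls <- function(data, init = NULL) {
  S <- data$substrate; v <- data$rate
  start <- if (!is.null(init) && is.finite(init$km) && init$km > 0 &&
               init$vmax > 0) {
    list(Vmax = init$vmax, Km = init$km)
  } else {
    list(Vmax = max(v) * 1.2, Km = stats::median(S))
  }
  fit <- nls(v ~ Vmax * S / (Km + S), start = start,
             control = stats::nls.control(warnOnly = FALSE,
                                          scaleOffset = 1))
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  flags <- character(0)
  if (cf["Km"] <= 0 || cf["Vmax"] <= 0) flags <- "fit_failure:nonpositive_parameter"
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  new_kinetic_fit(unname(cf["Km"]), unname(cf["Vmax"]),
                  unname(se["Km"]), unname(se["Vmax"]),
                  r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                  method = "nonlinear", flags = flags, coef = cf)
}

new_kinetic_fit <- function(km, vmax, km_se, vmax_se, r_squared, method,
                            flags, coef) {
  structure(list(km = km, vmax = vmax, km_se = km_se, vmax_se = vmax_se,
                 r_squared = r_squared, method = method, flags = flags,
                 coef = coef, alternative = NULL),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: Km = %.4g mM (SE %.2g), Vmax = %.4g (SE %.2g), r2 = %.4f\n",
              x$method, x$km, x$km_se, x$vmax, x$vmax_se, x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a calibration series
#'
#' @param amount Added (or external-standard) analyte amounts, >= 0; a
#'   standard-addition design must include the zero-spike sample.
#' @param response Detector responses, same length.
#' @param blank_sd Standard deviation of blank responses (for [lod_loq()]).
#' @param design `"standard_addition"` or `"external"`.
#' @return A `calibration_series`.
#' @export
calibration_series <- function(amount, response, blank_sd = 0,
                               design = c("standard_addition", "external")) {
  design <- match.arg(design)
  stopifnot(length(amount) == length(response))
  if (any(amount < 0)) stop("amounts must be >= 0")
  if (design == "standard_addition" && !any(amount == 0)) {
    stop("a standard-addition series must include the zero-spike sample")
  }
  if (length(amount) < 3) stop("need at least 3 calibration points")
  structure(list(amount = as.numeric(amount), response = as.numeric(response),
                 blank_sd = blank_sd, design = design),
            class = "calibration_series")
}

#' Standard-addition quantification
#'
#' Ordinary least squares of response on added amount; the endogenous
#' amount is the magnitude of the regression's x-intercept
#' (`intercept/slope`). Uncertainty comes from first-order propagation of
#' the slope/intercept covariance. Scaling all responses by a positive
#' constant leaves the estimate unchanged.
#'
#' @param series A [calibration_series()] with
#'   `design = "standard_addition"`.
#' @param tissue_mass Optional sample mass (g fresh weight) to convert the
#'   per-assay amount to a per-gram concentration.
#' @return A `quant_result`: `amount` (per assay), `amount_se`,
#'   `per_gram`, `per_gram_se`, `slope`, `intercept`, `sigma` (residual
#'   SD), `flags`.
#' @export
standard_addition <- function(series, tissue_mass = NULL) {
  stopifnot(inherits(series, "calibration_series"))
  if (series$design != "standard_addition") {
    stop("series design must be standard_addition")
  }
  fit <- lm(series$response ~ series$amount)
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  if (b1 <= 0) {
    stop("calibration failure: nonpositive slope (", signif(b1, 3), ")")
  }
  V <- suppressWarnings(vcov(fit))   # summary.lm warns on perfect fits
  est <- b0 / b1            # = |x-intercept|
  flags <- character(0)
  if (est < 0) flags <- "negative_endogenous_amount"
  se <- abs(est) * sqrt(V[1, 1] / b0^2 + V[2, 2] / b1^2 -
                          2 * V[1, 2] / (b0 * b1))
  per_gram <- if (!is.null(tissue_mass)) est / tissue_mass else NA_real_
  per_gram_se <- if (!is.null(tissue_mass)) se / tissue_mass else NA_real_
  structure(list(amount = est, amount_se = se,
                 per_gram = per_gram, per_gram_se = per_gram_se,
                 slope = b1, intercept = b0,
                 sigma = suppressWarnings(summary(fit))$sigma,
                 flags = flags),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> endogenous amount %.4g +/- %.2g per assay\n",
              x$amount, x$amount_se))
  if (!is.na(x$per_gram)) {
    cat(sprintf("  %.4g +/- %.2g per g fresh weight\n",
                x$per_gram, x$per_gram_se))
  }
  invisible(x)
}

#' Limits of detection and quantification
#'
#' The 3-sigma / 10-sigma convention: `lod = 3*blank_sd/slope`,
#' `loq = 10*blank_sd/slope`, both in amount units. The multipliers are
#' configurable (some labs use 3.3/10).
#'
#' @param slope Calibration slope (response per amount), > 0.
#' @param blank_sd Standard deviation of blank responses, >= 0.
#' @param multipliers Numeric pair `c(lod, loq)` of sigma multipliers.
#' @return Named numeric vector `c(lod = , loq = )`.
#' @export
lod_loq <- function(slope, blank_sd, multipliers = c(3, 10)) {
  if (slope <= 0) stop("calibration slope must be > 0")
  if (blank_sd < 0) stop("blank_sd must be >= 0")
  stopifnot(length(multipliers) == 2, multipliers[1] < multipliers[2])
  c(lod = multipliers[1] * blank_sd / slope,
    loq = multipliers[2] * blank_sd / slope)
}

#' Equimolar stoichiometry check for two reaction products
#'
#' @param product_a,product_b Measured amounts (>= 0).
#' @param tolerance Relative tolerance on the ratio (default 0.15).
#' @return A list with `ratio` (a/b) and `pass`.
#' @export
stoichiometry_check <- function(product_a, product_b, tolerance = 0.15) {
  stopifnot(product_a >= 0, product_b >= 0)
  if (product_b == 0) stop("undefined ratio: second product amount is zero")
  ratio <- product_a / product_b
  list(ratio = ratio, pass = abs(ratio - 1) <= tolerance)
}
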