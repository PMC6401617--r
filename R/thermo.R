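#' Van't Hoff extraction of association enthalpy and entropy
#'
#' Linear regression of \eqn{\ln K} on \eqn{1/T} (T in kelvin):
#' \deqn{\ln K = -\frac{\Delta H}{R}\frac{1}{T} + \frac{\Delta S}{R},}
#' so \eqn{\Delta H = -R \cdot slope} and \eqn{\Delta S = R \cdot intercept}
#' with \eqn{R = 8.314} J K^-1 mol^-1.  Temperatures are taken in degrees
#' Celsius and converted internally (T_K = T_C + 273.15).
#'
#' @param temp_c Temperatures in degrees Celsius (>= 2 distinct values).
#' @param k Equilibrium constants (L/mol, > 0), one per temperature.
#' @param k_sd Optional standard deviations of K, used when
#'   \code{weighted = TRUE} (weights \eqn{1/\sigma_{\ln K}^2} with
#'   \eqn{\sigma_{\ln K} = \sigma_K / K}).
#' @param weighted Logical; default unweighted regression.
#' @return Object of class \code{"vant_hoff_fit"}: \code{delta_h},
#'   \code{delta_h_se} (kJ/mol), \code{delta_s}, \code{delta_s_se}
#'   (J K^-1 mol^-1), \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n}.
#' @examples
#' fit_vant_hoff(c(5, 15, 25, 35, 45), c(8.0, 5.6, 4.1, 5.6, 6.8) * 1e5)
#' @export
fit_vant_hoff <- function(temp_c, k, k_sd = NULL, weighted = FALSE) {
  if (length(temp_c) != length(k)) stop("temp_c and k must match in length")
  if (length(unique(temp_c)) < 2L)
    stop("fit_vant_hoff: need >= 2 distinct temperatures")
  if (any(k <= 0)) stop("equilibrium constants must be positive")
  R <- 8.314
  inv_t <- 1 / (temp_c + 273.15)
  lnk <- log(k)
  w <- if (weighted) {
    if (is.null(k_sd)) stop("weighted fit requires k_sd")
    (k / k_sd)^2
  } else rep(1, length(k))
  fit <- stats::lm(lnk ~ inv_t, weights = w)
  cf <- suppressWarnings(summary(fit))$coefficients
  # with exactly 2 points the fit is exact: no residual dof, SEs are zero
  se_slope <- if (length(k) > 2) cf["inv_t", "Std. Error"] else 0
  se_int <- if (length(k) > 2) cf["(Intercept)", "Std. Error"] else 0
  slope <- cf["inv_t", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  out <- list(delta_h = -R * slope / 1000,
              delta_h_se = R * se_slope / 1000,
              delta_s = R * intercept,
              delta_s_se = R * se_int,
              slope = slope, intercept = intercept,
              r_squared = suppressWarnings(summary(fit))$r.squared,
              n = length(k))
  class(out) <- "vant_hoff_fit"
  out
}

#' Gibbs free energy from fitted enthalpy and entropy
#'
#' \eqn{\Delta G(T) = \Delta H - T \Delta S}, kJ/mol, at the requested
#' temperature.
#'
#' @param fit A \code{\link{fit_vant_hoff}} result.
#' @param temp_c Temperature in degrees Celsius (default 25).
#' @return Delta G in kJ/mol.
#' @export
delta_g <- function(fit, temp_c = 25) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  fit$delta_h - (temp_c + 273.15) * fit$delta_s / 1000
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("van't Hoff fit (n =", x$n, "temperatures)\n")
  cat(sprintf("  dH = %.2f +/- %.2f kJ/mol\n", x$delta_h, x$delta_h_se))
  cat(sprintf("  dS = %.1f +/- %.1f J K^-1 mol^-1  (R^2 = %.3f)\n",
              x$delta_s, x$delta_s_se, x$r_squared))
  invisible(x)
}
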