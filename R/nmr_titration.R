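#' Predicted chemical shift along a 1:1 titration
#'
#' Fast-exchange observed shift of a host resonance during addition of a
#' guest, using the exact quadratic 1:1 speciation (no excess-guest
#' approximation):
#' \deqn{\delta_{pred} = \delta_{free} + \Delta\delta_{max}\,[HG]/H_t,}
#' with \eqn{[HG]} from \code{\link{hg_speciation}}.
#'
#' @param h_total Total host concentration, mol/L (constant).
#' @param g_total Total guest concentration(s), mol/L.
#' @param k_assoc Association constant, L/mol.
#' @param delta_free Free-host chemical shift, ppm.
#' @param delta_max Limiting complexation-induced shift (ppm; sign
#'   preserved, \eqn{\Delta\delta = \delta_{complex} - \delta_{free}}).
#' @return Predicted shift(s), ppm.
#' @export
titration_model <- function(h_total, g_total, k_assoc, delta_free,
                            delta_max) {
  sp <- hg_speciation(h_total, g_total, k_assoc)
  delta_free + delta_max * sp$complex / sp$h_total
}

#' Fit an NMR titration to a 1:1 binding model
#'
#' Nonlinear least squares over \code{(log K_a, delta_free, delta_max)} per
#' tracked resonance, with K_a shared across resonances when several shift
#' columns are supplied (global fit, the default).  The binding isotherm
#' uses the exact quadratic speciation throughout.
#'
#' Host stoichiometry modes:
#' \describe{
#'   \item{\code{"monomer"}}{the analytical host concentration is used as
#'     is (ordinary 1:1 host:guest fit).}
#'   \item{\code{"dimer"}}{the host self-dimerizes and the \emph{dimer} is
#'     the 1:1 binding partner (a 2:1 stoichiometry on the monomer basis).
#'     The effective host concentration is \eqn{C_t x_{molecule}/2}
#'     computed via \code{\link{dimer_speciation}} when \code{k_dim} is
#'     supplied, or \eqn{C_t/2} when dimerization is taken as saturated.}
#' }
#'
#' @param h_total Total host concentration (mol/L, monomer/analytical
#'   basis), constant across points.
#' @param g_total Guest concentrations (mol/L), non-decreasing.
#' @param shifts Observed shifts: numeric vector (one resonance) or matrix
#'   / data.frame with one column per tracked resonance (ppm).
#' @param mode \code{"monomer"} or \code{"dimer"} (see above).
#' @param k_dim Dimerization constant (L/mol), used only in dimer mode to
#'   compute the effective dimer concentration; \code{NULL} assumes
#'   saturated dimerization.
#' @param global Logical; share K_a across resonances (default) or fit each
#'   independently.
#' @return Object of class \code{"titration_fit"}: \code{k_assoc},
#'   \code{k_assoc_se} (L/mol), \code{delta_free}, \code{delta_max} (per
#'   resonance, ppm), \code{residuals}, \code{saturation_final} (fraction
#'   of host bound at the last point), \code{weak_identifiability} (TRUE
#'   when that fraction is < 0.5), \code{h_effective}, \code{converged}.
#'   When \code{global = FALSE}, a list of such objects (one per
#'   resonance).
#' @export
fit_titration <- function(h_total, g_total, shifts,
                          mode = c("monomer", "dimer"), k_dim = NULL,
                          global = TRUE) {
  mode <- match.arg(mode)
  shifts <- as.matrix(shifts)
  npt <- length(g_total)
  if (nrow(shifts) != npt) stop("shifts must have one row per guest point")
  if (npt < 6L) stop("fit_titration: need >= 6 titration points")
  if (is.unsorted(g_total)) stop("guest concentrations must be non-decreasing")
  if (length(h_total) != 1L || h_total <= 0)
    stop("h_total must be a positive scalar")

  h_eff <- switch(mode,
    monomer = h_total,
    dimer = if (is.null(k_dim)) h_total / 2
            else h_total * dimer_speciation(h_total, k_dim)$x_molecule / 2)

  if (!global && ncol(shifts) > 1L) {
    fits <- lapply(seq_len(ncol(shifts)), function(j)
      fit_titration(h_total, g_total, shifts[, j, drop = FALSE],
                    mode = mode, k_dim = k_dim, global = TRUE))
    names(fits) <- colnames(shifts)
    return(fits)
  }

  nres <- ncol(shifts)
  # deterministic start: K from the guest concentration at half shift change,
  # delta_free from the first point, delta_max from the observed span
  d0 <- shifts[1, ]
  dspan <- shifts[npt, ] - d0
  mid_j <- which.max(abs(dspan))
  mid <- d0[mid_j] + dspan[mid_j] / 2
  g_half <- g_total[which.min(abs(shifts[, mid_j] - mid))]
  k0 <- 1 / max(g_half - h_eff / 2, min(g_total[g_total > 0]) / 10,
                .Machine$double.eps)
  par0 <- c(log(k0), as.numeric(d0), as.numeric(dspan))

  resid_fun <- function(p) {
    k <- exp(p[1])
    dfree <- p[1 + seq_len(nres)]
    dmax <- p[1 + nres + seq_len(nres)]
    pred <- vapply(seq_len(nres), function(j)
      titration_model(h_eff, g_total, k, dfree[j], dmax[j]),
      numeric(npt))
    as.numeric(pred - shifts)
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-13, ptol = 1e-13))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit_titration: did not fully converge (info=", fit$info, ")")
  p <- fit$par
  k <- exp(p[1])
  dof <- npt * nres - length(par0)
  k_se <- tryCatch({
    s2 <- fit$deviance / max(dof, 1L)
    covm <- s2 * solve(fit$hessian / 2)
    k * sqrt(covm[1, 1])
  }, error = function(e) NA_real_)

  sat <- hg_speciation(h_eff, g_total[npt], k)$complex / h_eff
  if (sat < 0.5)
    warning(sprintf(
      "fit_titration: only %.0f%% of host bound at the final point; ",
      100 * sat), "K_a is weakly identified")
  out <- list(k_assoc = k, k_assoc_se = k_se,
              delta_free = stats::setNames(p[1 + seq_len(nres)],
                                           colnames(shifts)),
              delta_max = stats::setNames(p[1 + nres + seq_len(nres)],
                                          colnames(shifts)),
              residuals = matrix(fit$fvec, npt, nres,
                                 dimnames = list(NULL, colnames(shifts))),
              saturation_final = sat,
              weak_identifiability = sat < 0.5,
              h_effective = h_eff, mode = mode,
              converged = converged, n = npt)
  class(out) <- "titration_fit"
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("1:1 NMR titration fit (%s-host mode, n = %d points)\n",
              x$mode, x$n))
  cat(sprintf("  K_a = %.3g +/- %.2g L/mol  (effective host %.3g M)\n",
              x$k_assoc, x$k_assoc_se, x$h_effective))
  for (j in seq_along(x$delta_max))
    cat(sprintf("  resonance %s: delta_free = %.4f ppm, ddelta_max = %+.4f ppm\n",
                if (is.null(names(x$delta_max))) j else names(x$delta_max)[j],
                x$delta_free[j], x$delta_max[j]))
  cat(sprintf("  host bound at final point: %.0f%%\n",
              100 * x$saturation_final))
  invisible(x)
}
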