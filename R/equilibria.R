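#' Monomer-dimer speciation by exact mass action
#'
#' Solves the self-association equilibrium 2M <=> D at total concentration
#' \code{c_total} (monomer-unit basis, mol/L) with association constant
#' \code{k_dim} (L/mol).  The monomer concentration is the positive root of
#' the mass-balance quadratic \eqn{2 K [M]^2 + [M] - C_t = 0},
#' \deqn{[M] = \frac{-1 + \sqrt{1 + 8 K C_t}}{4K},}
#' and the dimer follows from \eqn{[D] = ([C_t] - [M])/2}.
#'
#' Two dimer-fraction conventions are in routine use and both are returned:
#' the fraction of \emph{molecules} residing in the dimer,
#' \eqn{x_{molecule} = 2[D]/C_t}, and the fraction of \emph{species},
#' \eqn{x_{species} = [D]/([M]+[D])}.  They differ appreciably whenever
#' dimerization is partial, so callers must pick the one their observable
#' reports.
#'
#' @param c_total Total concentration (mol/L, monomer-unit basis).  Vectorized.
#' @param k_dim Dimerization association constant (L/mol).  Scalar.
#' @return A data.frame of class \code{"dimer_speciation"} with columns
#'   \code{c_total}, \code{monomer}, \code{dimer}, \code{x_molecule},
#'   \code{x_species}.
#' @examples
#' sp <- dimer_speciation(1.5e-4, 4.1e5)
#' sp$x_molecule   # ~0.914: >90% of molecules are dimerized
#' @export
dimer_speciation <- function(c_total, k_dim) {
  if (any(c_total < 0) || length(k_dim) != 1L || k_dim < 0 ||
      any(!is.finite(c_total)) || !is.finite(k_dim))
    stop("dimer_speciation: c_total and k_dim must be finite and non-negative")
  if (k_dim == 0) {
    m <- c_total
  } else {
    # expm1-style guard not needed: 8*K*Ct >= 0 and the root is well-conditioned
    m <- (-1 + sqrt(1 + 8 * k_dim * c_total)) / (4 * k_dim)
    # when 8*K*Ct << 1 cancellation can bite; refine with one Newton step
    # on f(m) = 2K m^2 + m - Ct (derivative 4K m + 1 > 0)
    f <- 2 * k_dim * m^2 + m - c_total
    m <- m - f / (4 * k_dim * m + 1)
    m <- pmin(pmax(m, 0), c_total)
  }
  d <- (c_total - m) / 2
  out <- data.frame(
    c_total = c_total,
    monomer = m,
    dimer = d,
    x_molecule = ifelse(c_total > 0, 2 * d / c_total, 0),
    x_species = ifelse(m + d > 0, d / (m + d), 0)
  )
  class(out) <- c("dimer_speciation", "data.frame")
  out
}

#' 1:1 host-guest speciation (exact quadratic)
#'
#' Solves H + G <=> HG with association constant \code{k_assoc}:
#' \eqn{x = [HG]} is the physical root of
#' \eqn{K (H_t - x)(G_t - x) = x}, i.e.
#' \deqn{x = \frac{(H_t + G_t + 1/K) - \sqrt{(H_t + G_t + 1/K)^2 - 4 H_t G_t}}{2}.}
#' No fast-exchange or excess-guest approximation is made.
#'
#' @param h_total Total host concentration (mol/L).
#' @param g_total Total guest concentration (mol/L).  Vectorized together
#'   with \code{h_total} under the usual recycling rules.
#' @param k_assoc Association constant (L/mol), scalar.
#' @return data.frame of class \code{"binding_speciation"} with columns
#'   \code{h_total}, \code{g_total}, \code{complex}, \code{free_host},
#'   \code{free_guest}.
#' @export
hg_speciation <- function(h_total, g_total, k_assoc) {
  if (any(h_total < 0) || any(g_total < 0) ||
      length(k_assoc) != 1L || k_assoc < 0)
    stop("hg_speciation: inputs must be non-negative")
  n <- max(length(h_total), length(g_total))
  h <- rep_len(h_total, n); g <- rep_len(g_total, n)
  if (k_assoc == 0) {
    x <- numeric(n)
  } else {
    b <- h + g + 1 / k_assoc
    disc <- b^2 - 4 * h * g
    x <- (b - sqrt(pmax(disc, 0))) / 2
    # the subtraction loses precision when 4hg << b^2; rationalize:
    x2 <- (2 * h * g) / (b + sqrt(pmax(disc, 0)))
    x <- ifelse(is.finite(x2), x2, x)
    x <- pmin(x, pmin(h, g))
  }
  out <- data.frame(h_total = h, g_total = g, complex = x,
                    free_host = h - x, free_guest = g - x)
  class(out) <- c("binding_speciation", "data.frame")
  out
}

#' Coupled dimerization + dimer:guest speciation
#'
#' Solves the coupled system in which the host self-dimerizes and the dimer
#' binds one guest (the 2:1 host:guest stoichiometry on a monomer basis):
#' \deqn{[D] = K_D [M]^2, \quad [DG] = K_a [D][G],}
#' \deqn{[M] + 2[D] + 2[DG] = C_t, \quad [G] + [DG] = G_t.}
#' Reduction to a single unknown: for given \eqn{[M]},
#' \eqn{[D] = K_D [M]^2} and the guest balance gives
#' \eqn{[G] = G_t / (1 + K_a [D])}; the host mass-balance residual is then
#' monotone in \eqn{[M]} and is solved by bracketed root-finding
#' (\code{uniroot}) on \eqn{[0, C_t]} followed by Newton polishing to a
#' relative mass-balance residual below 1e-10.
#'
#' @param c_total Total host (mol/L, monomer basis), scalar.
#' @param g_total Total guest (mol/L), scalar.
#' @param k_dim Dimerization constant (L/mol).
#' @param k_assoc_dimer Association constant of D + G <=> DG (L/mol).
#' @return list of class \code{"coupled_speciation"} with elements
#'   \code{monomer}, \code{dimer}, \code{free_guest}, \code{complex},
#'   \code{residual} (worst relative mass-balance residual).
#' @export
coupled_speciation <- function(c_total, g_total, k_dim, k_assoc_dimer) {
  stopifnot(length(c_total) == 1L, length(g_total) == 1L)
  if (c_total < 0 || g_total < 0 || k_dim < 0 || k_assoc_dimer < 0)
    stop("coupled_speciation: inputs must be non-negative")
  if (c_total == 0) {
    out <- list(monomer = 0, dimer = 0, free_guest = g_total, complex = 0,
                residual = 0)
    class(out) <- "coupled_speciation"
    return(out)
  }
  host_residual <- function(m) {
    d <- k_dim * m^2
    g <- g_total / (1 + k_assoc_dimer * d)
    dg <- k_assoc_dimer * d * g
    m + 2 * d + 2 * dg - c_total
  }
  # residual is strictly increasing in m; brackets [0, c_total]
  r <- stats::uniroot(host_residual, c(0, c_total), tol = 1e-14 * c_total,
                      maxiter = 200L)
  m <- r$root
  # Newton polish on the host balance (derivative computed analytically)
  for (i in 1:8) {
    d <- k_dim * m^2
    g <- g_total / (1 + k_assoc_dimer * d)
    dg <- k_assoc_dimer * d * g
    f <- m + 2 * d + 2 * dg - c_total
    dd_dm <- 2 * k_dim * m
    dg_dm <- k_assoc_dimer * g_total * dd_dm / (1 + k_assoc_dimer * d)^2
    fp <- 1 + 2 * dd_dm + 2 * dg_dm
    step <- f / fp
    m_new <- m - step
    if (!is.finite(m_new) || m_new < 0) break
    m <- m_new
    if (abs(step) < 1e-16 * max(m, c_total)) break
  }
  d <- k_dim * m^2
  g <- g_total / (1 + k_assoc_dimer * d)
  dg <- k_assoc_dimer * d * g
  res_host <- abs(m + 2 * d + 2 * dg - c_total) / c_total
  res_guest <- if (g_total > 0) abs(g + dg - g_total) / g_total else 0
  residual <- max(res_host, res_guest)
  if (residual > 1e-10)
    stop(sprintf(
      "coupled_speciation failed to converge: relative residual %.3e (M=%.3e)",
      residual, m))
  out <- list(monomer = m, dimer = d, free_guest = g, complex = dg,
              residual = residual)
  class(out) <- "coupled_speciation"
  out
}
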