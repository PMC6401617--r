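# Seeded generators for every input the analysis chain consumes.
#
# Each generator draws from its own RNG stream, derived from (seed, kind),
# so datasets simulated for different stages under the same master seed are
# statistically independent and each stage can be tested in isolation.
# The caller's RNG state is saved and restored.

.kind_offsets <- c(decay = 101L, isotherm = 211L, titration = 307L,
                   vant_hoff = 401L, quench = 503L)

.with_stream <- function(seed, kind, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000000L) * 1000L + .kind_offsets[[kind]])
  eval.parent(substitute(expr))
}

#' Simulate a TCSPC decay histogram and matching IRF
#'
#' Builds a Gaussian instrument response on a uniform channel grid,
#' reconvolves it with a multi-exponential truth decay, scales the expected
#' curve so the maximum expected count equals \code{peak_counts}, and
#' (optionally) draws per-channel Poisson counts.  Defaults mirror a
#' typical single-photon-counting acquisition: a 200 ns window with 10,000
#' counts at the intensity maximum.
#'
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @param lifetimes,amplitudes Truth decay components (ns; relative
#'   amplitudes).
#' @param window_ns Acquisition window length (ns).
#' @param n_channels Number of channels.
#' @param peak_counts Expected counts in the peak channel.
#' @param irf_fwhm_ns Full width at half maximum of the Gaussian IRF (ns).
#' @param irf_t0_ns Position of the IRF maximum within the window (ns).
#' @param scatter_fraction Fraction of the expected signal carried by an
#'   IRF-shaped scatter component (default 0).
#' @param background Flat background expected counts per channel.
#' @param poisson Logical; \code{FALSE} returns the noiseless expectation
#'   (rounded to counts only for the histogram container's benefit is NOT
#'   done - exact expectations are kept).
#' @return List with \code{decay} and \code{irf}
#'   (\code{\link{decay_histogram}}; for \code{poisson = FALSE} the decay
#'   counts are the exact expectations), plus \code{truth}
#'   (\code{\link{multiexp_model}}) and \code{expected} (noiseless curve).
#' @export
simulate_decay <- function(seed, lifetimes = c(2.3, 11.6),
                           amplitudes = c(1, 1), window_ns = 200,
                           n_channels = 1024L, peak_counts = 10000,
                           irf_fwhm_ns = 1, irf_t0_ns = 10,
                           scatter_fraction = 0, background = 0,
                           poisson = TRUE) {
  if (n_channels < 4L) stop("simulate_decay: degenerate acquisition grid")
  dt <- window_ns / n_channels
  tgrid <- (seq_len(n_channels) - 0.5) * dt
  irf_sigma <- irf_fwhm_ns / (2 * sqrt(2 * log(2)))
  irf_shape <- exp(-0.5 * ((tgrid - irf_t0_ns) / irf_sigma)^2)
  irf_counts <- round(irf_shape / max(irf_shape) * peak_counts)
  irf <- decay_histogram(tgrid, irf_counts)
  truth <- multiexp_model(amplitudes, lifetimes,
                          scatter_fraction = scatter_fraction)
  mu <- reconvolve(irf, truth)
  mu <- mu / max(mu) * peak_counts + background
  counts <- if (poisson) .with_stream(seed, "decay", stats::rpois(length(mu), mu))
            else mu
  list(decay = decay_histogram(tgrid, counts), irf = irf,
       truth = truth, expected = mu)
}

#' Simulate a dimerization isotherm dataset
#'
#' Average lifetime versus total concentration from
#' \code{\link{isotherm_model}} plus Gaussian lifetime noise.  The default
#' design is 12 log-spaced concentrations over 1e-6 to 3e-4 M, covering the
#' rise and plateau of a strongly dimerizing host.
#'
#' @param seed Integer seed.
#' @param concentrations Total concentrations, mol/L.
#' @param k_dim,tau_mon,tau_dim Truth parameters (L/mol; ns; ns).
#' @param sigma_tau Gaussian lifetime noise, ns.
#' @param temperature Temperature label, degrees C.
#' @return data.frame with columns \code{conc_M}, \code{avg_tau_ns} and
#'   attribute \code{temperature_C}.
#' @export
simulate_isotherm <- function(seed,
                              concentrations = 10^seq(log10(1e-6),
                                                      log10(3e-4),
                                                      length.out = 12),
                              k_dim = 4.1e5, tau_mon = 2.3, tau_dim = 11.6,
                              sigma_tau = 0.2, temperature = 25) {
  mu <- isotherm_model(concentrations, k_dim, tau_mon, tau_dim)
  tau <- if (sigma_tau > 0)
    .with_stream(seed, "isotherm",
                 mu + stats::rnorm(length(mu), 0, sigma_tau))
  else mu
  out <- data.frame(conc_M = concentrations, avg_tau_ns = tau)
  attr(out, "temperature_C") <- temperature
  out
}

#' Simulate an NMR titration dataset
#'
#' Observed chemical shifts along a guest-into-host titration from
#' \code{\link{titration_model}} plus Gaussian shift noise.  \code{h_total}
#' is the concentration of the actual 1:1 binding partner (the dimer
#' concentration in dimer-host experiments).
#'
#' @param seed Integer seed.
#' @param h_total Host (binding partner) concentration, mol/L.
#' @param guest_totals Guest concentrations, mol/L (default 15 points from
#'   0 to 95% saturation for the given truth).
#' @param k_assoc,delta_free,delta_max Truth parameters (L/mol; ppm; ppm).
#' @param sigma_shift Gaussian shift noise, ppm.
#' @return data.frame with columns \code{guest_total_M},
#'   \code{shift_ppm} and attribute \code{host_total_M}.
#' @export
simulate_titration <- function(seed, h_total = 2.5e-4, guest_totals = NULL,
                               k_assoc = 1.3e4, delta_free = 7.5,
                               delta_max = 0.05, sigma_shift = 0.002) {
  if (is.null(guest_totals))
    guest_totals <- titration_design(h_total, k_assoc, n_points = 15,
                                     saturation = 0.95)
  mu <- titration_model(h_total, guest_totals, k_assoc, delta_free,
                        delta_max)
  obs <- if (sigma_shift > 0)
    .with_stream(seed, "titration",
                 mu + stats::rnorm(length(mu), 0, sigma_shift))
  else mu
  out <- data.frame(guest_total_M = guest_totals, shift_ppm = obs)
  attr(out, "host_total_M") <- h_total
  out
}

#' Guest-concentration design reaching a target saturation
#'
#' Evenly spaced guest totals from 0 to the concentration at which the
#' exact 1:1 quadratic predicts the requested fraction of host bound:
#' for bound fraction s, \eqn{G_t = s H_t + s H_t / (K (1-s) H_t)}.
#'
#' @param h_total Host concentration, mol/L.
#' @param k_assoc Association constant, L/mol.
#' @param n_points Number of titration points (first is guest-free).
#' @param saturation Target bound fraction at the final point.
#' @return Guest concentrations, mol/L.
#' @export
titration_design <- function(h_total, k_assoc, n_points = 15,
                             saturation = 0.95) {
  stopifnot(saturation > 0, saturation < 1, k_assoc > 0, h_total > 0)
  x <- saturation * h_total
  g_max <- x + x / (k_assoc * (h_total - x))
  seq(0, g_max, length.out = n_points)
}

#' Simulate equilibrium constants across temperature
#'
#' \eqn{K(T) = \exp(-\Delta H/(R T) + \Delta S/R)} at the requested
#' temperatures with multiplicative lognormal noise of coefficient of
#' variation \code{noise_cv}.
#'
#' @param seed Integer seed.
#' @param temperatures_c Temperatures, degrees C (default 5-45 in 10
#'   degree steps).
#' @param delta_h Truth enthalpy, kJ/mol.
#' @param delta_s Truth entropy, J K^-1 mol^-1.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return data.frame with columns \code{temp_C}, \code{K}.
#' @export
simulate_vant_hoff <- function(seed, temperatures_c = seq(5, 45, by = 10),
                               delta_h = -2.5, delta_s = 102.7,
                               noise_cv = 0.1) {
  R <- 8.314
  t_k <- temperatures_c + 273.15
  k <- exp(-delta_h * 1000 / (R * t_k) + delta_s / R)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    k <- .with_stream(seed, "vant_hoff",
                      k * stats::rlnorm(length(k), -sdlog^2 / 2, sdlog))
  }
  data.frame(temp_C = temperatures_c, K = k)
}

#' Simulate a Stern-Volmer quenching series
#'
#' Lifetimes \eqn{\tau_0 / (1 + K_{SV} [Q])} over a quencher series plus
#' Gaussian lifetime noise.  Default quencher range 0-8 mM.
#'
#' @param seed Integer seed.
#' @param q_conc Quencher concentrations, mol/L (must include 0).
#' @param k_sv Truth Stern-Volmer constant, L/mol.
#' @param tau0 Unquenched lifetime, ns.
#' @param sigma_tau Gaussian lifetime noise, ns.
#' @return data.frame with columns \code{q_conc_M}, \code{avg_tau_ns}.
#' @export
simulate_quench <- function(seed, q_conc = seq(0, 8e-3, length.out = 9),
                            k_sv = 15, tau0 = 10.5, sigma_tau = 0) {
  mu <- tau0 / (1 + k_sv * q_conc)
  tau <- if (sigma_tau > 0)
    .with_stream(seed, "quench", mu + stats::rnorm(length(mu), 0, sigma_tau))
  else mu
  data.frame(q_conc_M = q_conc, avg_tau_ns = tau)
}
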