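#' Inner-filter correction of a fluorescence intensity
#'
#' Corrects an observed steady-state intensity for primary and secondary
#' inner-filter attenuation using the absorbances at the excitation and
#' emission wavelengths:
#' \deqn{I_{corr} = I_{obs} \, 10^{(A_{ex} + A_{em})/2}.}
#'
#' @param intensity Observed intensity (arbitrary units, > 0).  Vectorized.
#' @param a_ex Absorbance at the excitation wavelength (>= 0).
#' @param a_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected intensity, same units as \code{intensity}; always
#'   >= the observed value for non-negative absorbances.
#' @examples
#' correct_inner_filter(2.0, 0.1, 0.1)  # 2 * 10^0.1
#' @export
correct_inner_filter <- function(intensity, a_ex, a_em) {
  if (any(intensity <= 0)) stop("intensity must be positive")
  if (any(a_ex < 0) || any(a_em < 0)) stop("absorbances must be non-negative")
  intensity * 10^((a_ex + a_em) / 2)
}

#' Multi-exponential decay model
#'
#' Container for a sum-of-exponentials emission decay
#' \eqn{I(t) = \sum_i A_i e^{-t/\tau_i}} with optional IRF-shaped scatter
#' term.  Lifetimes are stored in ascending order (amplitudes reordered
#' accordingly).
#'
#' @param amplitudes Pre-exponential factors A_i (each > 0).
#' @param lifetimes Lifetimes tau_i in ns (each > 0), same length.
#' @param scatter_fraction Optional fraction in [0, 1) of the total signal
#'   carried by an IRF-shaped scatter component (excluded from average
#'   lifetime and fractional contributions).
#' @return Object of class \code{"multiexp_model"}.
#' @export
multiexp_model <- function(amplitudes, lifetimes, scatter_fraction = 0) {
  if (length(amplitudes) != length(lifetimes) || length(lifetimes) < 1L)
    stop("amplitudes and lifetimes must be non-empty and of equal length")
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)")
  ord <- order(lifetimes)
  structure(list(amplitudes = amplitudes[ord], lifetimes = lifetimes[ord],
                 n_components = length(lifetimes),
                 scatter_fraction = scatter_fraction),
            class = "multiexp_model")
}

#' Evaluate a multi-exponential decay on a time grid
#'
#' @param model A \code{\link{multiexp_model}}.
#' @param times Times in ns (>= 0).
#' @return Intensity at each time; at t = 0 this is \code{sum(amplitudes)}.
#' @export
decay_model <- function(model, times) {
  stopifnot(inherits(model, "multiexp_model"))
  if (any(times < 0)) stop("times must be non-negative")
  out <- numeric(length(times))
  for (i in seq_len(model$n_components))
    out <- out + model$amplitudes[i] * exp(-times / model$lifetimes[i])
  out
}

#' Amplitude-weighted average lifetime of a multi-exponential decay
#'
#' \deqn{\langle\tau\rangle = \sum_i A_i \tau_i^2 / \sum_i A_i \tau_i.}
#' This is the intensity-weighted mean: each component's lifetime weighted by
#' its share of the steady-state intensity.
#'
#' @inheritParams decay_model
#' @return Average lifetime in ns, bounded by the extreme component lifetimes.
#' @export
average_lifetime <- function(model) {
  stopifnot(inherits(model, "multiexp_model"))
  denom <- sum(model$amplitudes * model$lifetimes)
  if (denom <= 0) stop("average_lifetime: all amplitudes are zero")
  sum(model$amplitudes * model$lifetimes^2) / denom
}

#' Fractional intensity contributions of decay components
#'
#' \deqn{f_i = A_i \tau_i / \sum_j A_j \tau_j,} the fraction of steady-state
#' intensity carried by each component; the f_i sum to 1.
#'
#' @inheritParams decay_model
#' @return Numeric vector of fractions, one per component, summing to 1.
#' @export
fractional_contributions <- function(model) {
  stopifnot(inherits(model, "multiexp_model"))
  w <- model$amplitudes * model$lifetimes
  s <- sum(w)
  if (s <= 0) stop("fractional_contributions: all amplitudes are zero")
  w / s
}

#' Intensity-weighted two-species average lifetime
#'
#' For a dilute mixture of two non-interacting emitters with intensity
#' fractions f1, f2 (f1 + f2 = 1) and lifetimes tau1, tau2:
#' \eqn{\langle\tau\rangle = f_1 \tau_1 + f_2 \tau_2}.
#'
#' @param f1,f2 Intensity fractions summing to 1 (tolerance 1e-8).
#' @param tau1,tau2 Lifetimes in ns.
#' @return Average lifetime in ns.
#' @export
two_state_average <- function(f1, tau1, f2, tau2) {
  if (any(abs(f1 + f2 - 1) > 1e-8))
    stop("two_state_average: fractions must sum to 1")
  f1 * tau1 + f2 * tau2
}

#' Decay histogram (TCSPC)
#'
#' Binned photon counts on a uniform time grid, for either an emission decay
#' or an instrument response function (IRF).
#'
#' @param channel_times Channel centre times in ns, strictly increasing and
#'   uniformly spaced.
#' @param counts Non-negative counts per channel, same length.
#' @return Object of class \code{"decay_histogram"} with fields
#'   \code{channel_times}, \code{counts}, \code{dt} (channel width, ns),
#'   \code{window_length} (ns), \code{peak_counts}.
#' @export
decay_histogram <- function(channel_times, counts) {
  n <- length(channel_times)
  if (n < 2L || length(counts) != n)
    stop("channel_times and counts must have equal length >= 2")
  dt <- diff(channel_times)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("channel_times must be strictly increasing and uniformly spaced")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(channel_times = channel_times, counts = counts,
                 dt = dt[1],
                 window_length = channel_times[n] - channel_times[1] + dt[1],
                 peak_counts = max(counts)),
            class = "decay_histogram")
}

#' Reconvolve a decay model with a measured IRF
#'
#' Discrete linear (causal, zero-padded) convolution of the unit-normalized
#' IRF with the decay model evaluated on the shared channel grid, plus an
#' optional IRF-shaped scatter term carrying \code{scatter_fraction} of the
#' total expected signal.
#'
#' @param irf A \code{\link{decay_histogram}} holding the instrument
#'   response.
#' @param model A \code{\link{multiexp_model}}.
#' @param times Optional channel grid; defaults to the IRF grid.  Must match
#'   the IRF grid when a target histogram is being fitted.
#' @return Expected (model) counts per channel, same length as the grid.
#' @export
reconvolve <- function(irf, model, times = NULL) {
  stopifnot(inherits(irf, "decay_histogram"), inherits(model, "multiexp_model"))
  if (is.null(times)) times <- irf$channel_times
  n <- length(times)
  if (n != length(irf$channel_times) ||
      max(abs(times - irf$channel_times)) > 1e-9 * irf$dt)
    stop("reconvolve: decay and IRF must share the channel grid")
  irf_norm <- irf$counts / sum(irf$counts)
  t_rel <- times - times[1]
  dk <- decay_model(model, t_rel)
  # causal linear convolution, first n terms
  conv <- stats::convolve(dk, rev(irf_norm), type = "open")[seq_len(n)]
  conv <- pmax(conv, 0)
  if (model$scatter_fraction > 0) {
    s <- model$scatter_fraction
    tot <- sum(conv)
    conv <- (1 - s) * conv + s * tot * irf_norm
  }
  conv
}

#' Fit a TCSPC decay by iterative reconvolution
#'
#' Weighted nonlinear least squares of the reconvolved multi-exponential
#' model against a measured decay histogram, with Neyman (counting) weights
#' \eqn{1/\max(N_k, 1)}.  Optimization runs over log-lifetimes and
#' log-amplitudes (Levenberg-Marquardt, \code{minpack.lm}), which enforces
#' positivity and keeps lifetime ratios well conditioned.
#'
#' Initialization is deterministic: lifetimes log-spaced over
#' [channel width, window/2], amplitudes set from the peak counts, so
#' repeated fits of the same data are identical.
#'
#' @param decay A \code{\link{decay_histogram}} with the measured decay.
#' @param irf A \code{\link{decay_histogram}} with the instrument response
#'   on the same channel grid.
#' @param n_components Number of exponential components (1-3).
#' @param fit_range Either \code{"tail"} (default: from the peak channel to
#'   the last channel with counts >= max(10, peak/1000)), \code{"full"}
#'   (all channels), or an integer vector \code{c(lo, hi)} of channel
#'   indices.
#' @param scatter Logical; include an IRF-shaped scatter component (its
#'   fraction is fitted, and it is excluded from the reported average
#'   lifetime and fractional contributions).  Only meaningful with
#'   \code{fit_range = "full"} since scatter rides the rising edge.
#' @return Object of class \code{"decay_fit"}: fields \code{model}
#'   (\code{multiexp_model}, lifetimes ascending), \code{average_lifetime},
#'   \code{fractional_contributions}, \code{reduced_chi_square},
#'   \code{residuals} (weighted, fit range only), \code{fit_range} (channel
#'   indices), \code{overparameterized} (TRUE when some component carries
#'   < 1% of the intensity), \code{converged}.
#' @export
fit_decay <- function(decay, irf, n_components = 2L, fit_range = "tail",
                      scatter = FALSE) {
  stopifnot(inherits(decay, "decay_histogram"),
            inherits(irf, "decay_histogram"))
  if (!n_components %in% 1:3)
    stop("n_components must be 1, 2 or 3")
  n <- length(decay$channel_times)
  if (length(irf$channel_times) != n ||
      max(abs(decay$channel_times - irf$channel_times)) > 1e-9 * decay$dt)
    stop("fit_decay: decay and IRF must share the channel grid")

  idx <- .resolve_fit_range(decay, fit_range)
  if (length(idx) < n_components * 2 + 2)
    stop("fit_decay: fit range is empty or too short")

  counts <- decay$counts
  w <- 1 / pmax(counts, 1)            # Neyman weights
  sw <- sqrt(w)

  # deterministic initialization
  tau0 <- exp(seq(log(decay$dt), log(decay$window_length / 2),
                  length.out = n_components + 2L))[2:(n_components + 1L)]
  a0 <- rep(decay$peak_counts / n_components, n_components)
  par0 <- c(log(a0), log(tau0))
  if (scatter) par0 <- c(par0, stats::qlogis(0.01))

  resid_fun <- function(p) {
    a <- exp(p[seq_len(n_components)])
    tau <- exp(p[n_components + seq_len(n_components)])
    sf <- if (scatter) stats::plogis(p[2 * n_components + 1]) else 0
    m <- multiexp_model(a, tau, scatter_fraction = sf)
    mu <- reconvolve(irf, m)
    ((mu - counts) * sw)[idx]
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  converged <- fit$info %in% 1:4
  p <- fit$par
  a <- exp(p[seq_len(n_components)])
  tau <- exp(p[n_components + seq_len(n_components)])
  sf <- if (scatter) stats::plogis(p[2 * n_components + 1]) else 0
  model <- multiexp_model(a, tau, scatter_fraction = sf)
  if (!converged)
    warning("fit_decay: Levenberg-Marquardt did not fully converge (info=",
            fit$info, "); returning best point")

  f <- fractional_contributions(model)
  res <- resid_fun(p)
  npar <- length(par0)
  out <- list(model = model,
              average_lifetime = average_lifetime(model),
              fractional_contributions = f,
              reduced_chi_square = sum(res^2) / (length(idx) - npar),
              residuals = res,
              fit_range = idx,
              overparameterized = any(f < 0.01) ||
                (model$n_components > 1 &&
                   any(tau[-1] / tau[-length(tau)] < 1.2)),
              converged = converged)
  class(out) <- "decay_fit"
  out
}

.resolve_fit_range <- function(decay, fit_range) {
  n <- length(decay$counts)
  if (is.character(fit_range)) {
    peak <- which.max(decay$counts)
    if (fit_range == "full") return(seq_len(n))
    if (fit_range == "tail") {
      thr <- max(10, decay$peak_counts / 1000)
      ok <- which(decay$counts >= thr)
      hi <- if (length(ok)) max(ok) else n
      return(seq(peak, max(hi, peak + 1L)))
    }
    stop("fit_range must be 'tail', 'full', or c(lo, hi)")
  }
  lo <- as.integer(fit_range[1]); hi <- as.integer(fit_range[2])
  if (lo < 1L || hi > n || hi <= lo) stop("invalid fit_range")
  seq(lo, hi)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("TCSPC reconvolution fit:", x$model$n_components, "component(s)\n")
  tab <- data.frame(tau_ns = x$model$lifetimes,
                    amplitude = x$model$amplitudes,
                    f = x$fractional_contributions)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("<tau> = %.3f ns, reduced chi^2 = %.3f\n",
              x$average_lifetime, x$reduced_chi_square))
  if (x$overparameterized)
    cat("warning: model appears over-parameterized (component with f < 1%)\n")
  invisible(x)
}

#' Steady-state fluorescence anisotropy
#'
#' \eqn{r = (I_{VV} - G I_{VH}) / (I_{VV} + 2 G I_{VH})} with the
#' instrumental factor \eqn{G = I_{HV} / I_{HH}}.
#'
#' @param i_vv,i_vh,i_hv,i_hh Polarized intensity components (> 0):
#'   first subscript is the excitation polarizer (V vertical, H horizontal),
#'   second the emission polarizer.
#' @return List with \code{r} and \code{g_factor}.
#' @export
anisotropy <- function(i_vv, i_vh, i_hv, i_hh) {
  if (any(c(i_vv, i_vh, i_hv, i_hh) <= 0))
    stop("anisotropy: all intensities must be positive")
  g <- i_hv / i_hh
  denom <- i_vv + 2 * g * i_vh
  if (any(denom == 0)) stop("anisotropy: zero denominator")
  list(r = (i_vv - g * i_vh) / denom, g_factor = g)
}
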