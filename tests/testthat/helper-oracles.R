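# Independent oracles, deliberately written without reference to the
# package's closed forms.

# monomer concentration for 2M <=> D by plain bisection on the mass balance
bisect_monomer <- function(c_total, k_dim, tol = 1e-15) {
  if (c_total == 0) return(0)
  f <- function(m) 2 * k_dim * m^2 + m - c_total
  lo <- 0; hi <- c_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * c_total) break
  }
  (lo + hi) / 2
}

# complex concentration for H + G <=> HG by bisection
bisect_complex <- function(h, g, k, tol = 1e-15) {
  if (k == 0 || h == 0 || g == 0) return(0)
  f <- function(x) k * (h - x) * (g - x) - x
  lo <- 0; hi <- min(h, g)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * min(h, g)) break
  }
  (lo + hi) / 2
}

# O(n^2) direct causal convolution of a kernel with a signal
direct_convolve <- function(kernel, signal) {
  n <- length(signal)
  out <- numeric(n)
  for (k in seq_len(n))
    for (j in seq_len(k))
      out[k] <- out[k] + kernel[j] * signal[k - j + 1]
  out
}
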