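#' @keywords internal
"_PACKAGE"

# Internal numeric helpers shared across modules.

#' Gaussian-smooth an irregularly sampled signal over time
#'
#' Values are interpolated onto a regular grid at the nominal sampling rate,
#' convolved with a discrete Gaussian kernel (truncated at 4 SD, renormalized
#' at the edges), and interpolated back to the original timestamps. This keeps
#' the cost linear in the number of samples while tolerating dropouts.
#'
#' @param t numeric vector of timestamps (seconds, increasing)
#' @param v numeric vector of values
#' @param sd kernel standard deviation in seconds; 0 disables smoothing
#' @param rate grid rate in Hz used for the regular resampling
#' @return smoothed values at `t`
#' @keywords internal
gauss_smooth_time <- function(t, v, sd, rate = 30) {
  if (sd <= 0 || length(t) < 3) return(v)
  dt <- 1 / rate
  grid <- seq(t[1], t[length(t)], by = dt)
  vg <- stats::approx(t, v, xout = grid, rule = 2)$y
  half <- max(1L, ceiling(4 * sd / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sd)
  kern <- kern / sum(kern)
  if (2 * half + 1 >= length(vg)) {
    # series shorter than the kernel: windowed sums everywhere
    num <- den <- rep(NA_real_, length(vg))
  } else {
    num <- stats::filter(vg, kern, sides = 2)
    den <- stats::filter(rep(1, length(vg)), kern, sides = 2)
  }
  # partial kernels at the edges: renormalize by the covered mass
  pad <- is.na(num)
  if (any(pad)) {
    for (i in which(pad)) {
      lo <- max(1L, i - half); hi <- min(length(vg), i + half)
      kk <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
      num[i] <- sum(vg[lo:hi] * kk)
      den[i] <- sum(kk)
    }
  }
  sm <- as.numeric(num) / as.numeric(den)
  stats::approx(grid, sm, xout = t, rule = 2)$y
}

#' Derive a child RNG seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

#' Weighted standardized third moment of a profile
#'
#' Skewness of a nonnegative weight profile `w` over positions `x`:
#' with normalized weights, \eqn{m_3 / m_2^{3/2}} of the induced distribution.
#' Returns NA if the profile has zero variance or zero mass.
#' @keywords internal
weighted_skewness <- function(x, w) {
  if (length(x) < 3 || sum(w) <= 0) return(NA_real_)
  w <- w / sum(w)
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  if (m2 <= 0) return(NA_real_)
  m3 <- sum(w * (x - mu)^3)
  m3 / m2^1.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a
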