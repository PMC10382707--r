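# IIR Butterworth band-pass design and zero-phase filtering.
#
# The design follows the classical analog-prototype route: Butterworth
# low-pass poles, low-pass -> band-pass transform (order doubles), bilinear
# transform with frequency prewarping. Filtering uses direct form II
# transposed with steady-state initial conditions and odd-reflection padding,
# so a forward + time-reversed pass has zero net phase shift.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Design a Butterworth band-pass filter
#'
#' @param order analog prototype order (the band-pass transform doubles it;
#'   a two-pass zero-phase application doubles the effective order again).
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in samples/s.
#' @return A list with numerator `b` and denominator `a` polynomial
#'   coefficients of the digital filter.
#' @export
butter_bandpass <- function(order = 5L, lo = 100, hi = 3000, fs) {
  stopifnot(order >= 1, lo > 0, hi > lo, fs > 2 * hi)
  fs2 <- 2 * fs
  wlo <- fs2 * tan(pi * lo / fs)
  whi <- fs2 * tan(pi * hi / fs)
  w0 <- sqrt(wlo * whi)
  bw <- whi - wlo
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each pole maps to a conjugate-ish pair
  disc <- sqrt((p_lp * bw)^2 / 4 - w0^2)
  p_bp <- c(p_lp * bw / 2 + disc, p_lp * bw / 2 - disc)
  # n zeros at s = 0, n at infinity; overall analog gain bw^order
  z_dig <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  p_dig <- (fs2 + p_bp) / (fs2 - p_bp)
  # bilinear gain at matched point: k * prod(fs2 - z)/prod(fs2 - p), zeros at 0
  k_dig <- Re(bw^order * fs2^order / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_dig)) * k_dig
  a <- Re(poly_from_roots(p_dig))
  list(b = b, a = a)
}

# Steady-state initial filter state (direct form II transposed) for a unit
# step input, same construction as the classical filtfilt implementations.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  A <- t(comp)
  B <- b[-1] / a[1] - (a[-1] / a[1]) * (b[1] / a[1])
  solve(diag(n) - A, B)
}

# Direct form II transposed filter applied columnwise to a matrix
# (samples x channels). `zi` is either a length-n vector (scaled by each
# channel's first sample) or an n x channels matrix used directly.
iir_filter <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  ns <- nrow(x)
  nc <- ncol(x)
  n <- length(a) - 1L
  b <- b / a[1]
  a <- a / a[1]
  z <- if (is.null(zi)) matrix(0, n, nc)
       else if (is.matrix(zi)) zi
       else zi %o% x[1, ]
  y <- matrix(0, ns, nc)
  for (i in seq_len(ns)) {
    xi <- x[i, ]
    yi <- b[1] * xi + z[1, ]
    if (n > 1) {
      z[1:(n - 1), ] <- z[2:n, , drop = FALSE] +
        outer(b[2:n], xi) - outer(a[2:n], yi)
    }
    z[n, ] <- b[n + 1] * xi - a[n + 1] * yi
    y[i, ] <- yi
  }
  y
}

#' Butterworth band-pass as second-order sections
#'
#' Same design as [butter_bandpass()], factored into biquad sections (each
#' with one zero at z = 1 and one at z = -1, a conjugate pole pair, and an
#' equal share of the overall gain). Cascaded biquads avoid the error
#' amplification of the expanded order-2N polynomial form.
#'
#' @inheritParams butter_bandpass
#' @return A `n_sections x 6` matrix, rows `(b0, b1, b2, 1, a1, a2)`.
#' @export
butter_bandpass_sos <- function(order = 5L, lo = 100, hi = 3000, fs) {
  stopifnot(order >= 1, lo > 0, hi > lo, fs > 2 * hi)
  fs2 <- 2 * fs
  wlo <- fs2 * tan(pi * lo / fs)
  whi <- fs2 * tan(pi * hi / fs)
  w0 <- sqrt(wlo * whi)
  bw <- whi - wlo
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  disc <- sqrt((p_lp * bw)^2 / 4 - w0^2)
  p_bp <- c(p_lp * bw / 2 + disc, p_lp * bw / 2 - disc)
  p_dig <- (fs2 + p_bp) / (fs2 - p_bp)
  k_dig <- Re(bw^order * fs2^order / prod(fs2 - p_bp))
  # group poles into conjugate (or real) pairs
  up <- p_dig[Im(p_dig) > 1e-12]
  re <- sort(Re(p_dig[abs(Im(p_dig)) <= 1e-12]))
  pairs <- c(lapply(up, function(p) c(p, Conj(p))),
             if (length(re)) lapply(seq_len(length(re) / 2), function(i)
               c(re[2 * i - 1] + 0i, re[2 * i] + 0i)))
  stopifnot(length(pairs) == order, k_dig > 0)
  g <- k_dig^(1 / order)
  t(vapply(pairs, function(pp) {
    a1 <- -Re(pp[1] + pp[2]); a2 <- Re(pp[1] * pp[2])
    c(g, 0, -g, 1, a1, a2)                # zeros at +1 and -1
  }, numeric(6)))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and then time-reversed, with odd-reflection
#' padding and steady-state initial conditions at each end, so the net group
#' delay is zero and the effective magnitude response is squared.
#'
#' @param b,a digital filter coefficients, e.g. from [butter_bandpass()].
#' @param x numeric vector, or samples x channels matrix.
#' @param padlen odd-reflection padding length per end (default
#'   `3 * max(length(a), length(b))`).
#' @return Filtered data with the shape of `x`.
#' @export
filtfilt2 <- function(b, a, x, padlen = NULL) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  ns <- nrow(x)
  padlen <- as.integer(padlen %||% (3L * max(length(a), length(b))))
  if (ns <= padlen)
    abort2("record too short for zero-phase filtering", "audiogain_short_record")
  zi <- lfilter_zi(b, a)
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[ns, ], padlen, ncol(x), byrow = TRUE) -
    x[(ns - 1):(ns - padlen), , drop = FALSE]
  ext <- rbind(top, x, bot)
  y <- iir_filter(b, a, ext, zi = zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- iir_filter(b, a, y, zi = zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- y[(padlen + 1):(padlen + ns), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Zero-phase filtering of a second-order-section cascade
#'
#' Applies [filtfilt2()] section by section; the net response is the squared
#' magnitude of the full cascade with zero phase, computed with biquad
#' numerical conditioning.
#'
#' @param sos section matrix from [butter_bandpass_sos()].
#' @param x numeric vector or samples x channels matrix.
#' @param padlen odd-reflection padding per end (default 33, matching the
#'   order-10 polynomial-form transient allowance).
#' @return Filtered data with the shape of `x`.
#' @export
sosfiltfilt <- function(sos, x, padlen = 33L) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  ns <- nrow(x)
  if (ns <= padlen)
    abort2("record too short for zero-phase filtering",
           "audiogain_short_record")
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[ns, ], padlen, ncol(x), byrow = TRUE) -
    x[(ns - 1):(ns - padlen), , drop = FALSE]
  y <- rbind(top, x, bot)
  one_pass <- function(m) {
    x0 <- m[1, ]
    scale <- 1
    for (s in seq_len(nrow(sos))) {
      b <- sos[s, 1:3]; a <- sos[s, 4:6]
      m <- iir_filter(b, a, m, zi = lfilter_zi(b, a) %o% (scale * x0))
      scale <- scale * sum(b) / sum(a)   # cumulative DC gain
    }
    m
  }
  y <- one_pass(y)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- one_pass(y)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- y[(padlen + 1):(padlen + ns), , drop = FALSE]
  if (vec) drop(y) else y
}

# Causal single-pass cascade.
sosfilt_causal <- function(sos, x) {
  vec <- is.null(dim(x))
  y <- as.matrix(x)
  for (s in seq_len(nrow(sos)))
    y <- iir_filter(sos[s, 1:3], sos[s, 4:6], y)
  if (vec) drop(y) else y
}

# Causal single-pass variant (steady-state initial state, no padding).
filt_causal <- function(b, a, x) {
  vec <- is.null(dim(x))
  y <- iir_filter(b, a, as.matrix(x))
  if (vec) drop(y) else y
}

#' Analytic magnitude response of a digital filter
#'
#' @param b,a filter coefficients.
#' @param f frequencies in Hz.
#' @param fs sampling rate in samples/s.
#' @param passes 1 for single-pass, 2 for the zero-phase two-pass response.
#' @return `|H(f)|^passes`, the independent oracle for pass-band and
#'   stop-band checks.
#' @export
filter_gain <- function(b, a, f, fs, passes = 2) {
  w <- exp(-1i * 2 * pi * f / fs)
  H <- vapply(w, function(z) {
    num <- sum(b * z^(seq_along(b) - 1))
    den <- sum(a * z^(seq_along(a) - 1))
    abs(num / den)
  }, 0)
  H^passes
}
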