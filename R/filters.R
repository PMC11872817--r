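# IIR filter design and zero-phase filtering.
#
# No DSP package is available as a dependency, so the small amount of classic
# filter machinery the pipeline needs is implemented here: Butterworth
# low/high/band-pass design via the bilinear transform, a second-order notch
# biquad, forward-backward (zero-phase) application, and the FFT-based
# analytic signal. The recursive inner loops run through stats::filter, which
# is C code.

# Expand a polynomial from its roots; returns real coefficients,
# highest order first, leading coefficient 1.
poly_from_roots <- function(roots) {
  coef <- 1
  for (r in roots) coef <- c(coef, 0) - c(0, coef * r)
  re <- Re(coef)
  if (max(abs(Im(coef))) > 1e-8 * max(abs(re), 1))
    stop("internal: complex polynomial coefficients (unpaired roots)")
  re
}

freq_response <- function(b, a, w) {
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(b * zz^(-(seq_along(b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(-(seq_along(a) - 1))), complex(1))
  num / den
}

#' Butterworth digital filter design
#'
#' Designs an order-`n` Butterworth filter by bilinear transform of the
#' analog prototype with frequency prewarping. For `type = "pass"` the
#' resulting digital filter has order `2n`.
#'
#' @param n prototype order (>= 1).
#' @param cutoff cutoff frequency in Hz (scalar for low/high, `c(low, high)`
#'   for pass).
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_design <- function(n, cutoff, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fs > 0, all(cutoff > 0), all(cutoff < fs / 2))
  if (type == "pass" && (length(cutoff) != 2 || cutoff[1] >= cutoff[2]))
    stop("bandpass cutoff must be c(low, high) with low < high")
  # analog Butterworth prototype poles (left half-plane, wc = 1)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(cutoff[1])
    sp <- p * wc
    sz <- complex(0)                       # zeros at infinity -> z = -1
    zeros_z <- rep(-1 + 0i, n)
  } else if (type == "high") {
    wc <- warp(cutoff[1])
    sp <- wc / p
    zeros_z <- rep(1 + 0i, n)              # zeros at s = 0 -> z = 1
  } else {
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    # s_lp -> (s^2 + w0^2) / (bw * s): each prototype pole yields two
    disc <- sqrt((bw * p / 2)^2 - w0^2 + 0i)
    sp <- c(bw * p / 2 + disc, bw * p / 2 - disc)
    zeros_z <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  }
  if (any(Re(sp) >= 0)) stop("filter design unstable (band too narrow?)")
  zp <- (2 * fs + sp) / (2 * fs - sp)      # bilinear transform
  a <- poly_from_roots(zp)
  b <- poly_from_roots(zeros_z)
  # normalize gain to 1 at the reference frequency
  wref <- switch(type,
    low  = 0,
    high = pi,
    pass = 2 * atan(sqrt(tan(pi * cutoff[1] / fs) * tan(pi * cutoff[2] / fs))))
  g <- abs(freq_response(b, a, wref))
  b <- b / g
  list(b = b / a[1], a = a / a[1],
       sos = sos_from_zpk(zeros_z, zp, wref))
}

# Group digital poles/zeros into second-order sections. A single expanded
# polynomial is numerically fragile here: the 0.1 Hz high-pass at 200 Hz has
# a 4-fold pole cluster at radius ~0.997, and coefficient rounding moves
# clustered roots by ~eps^(1/4), enough to push poles outside the unit
# circle. Biquad sections keep each conjugate pair exact.
sos_from_zpk <- function(zeros, poles, wref) {
  pair_up <- function(r) {
    cpx <- r[Im(r) > 1e-9]
    re <- sort(Re(r[abs(Im(r)) <= 1e-9]))
    out <- lapply(cpx, function(p) c(p, Conj(p)))
    while (length(re) >= 2) {
      out <- c(out, list(re[1:2])); re <- re[-(1:2)]
    }
    if (length(re) == 1) out <- c(out, list(re))
    out
  }
  pp <- pair_up(poles)
  pos <- zeros[Re(zeros) > 0]
  neg <- zeros[Re(zeros) <= 0]
  if (length(pos) > 0 && length(neg) > 0) {
    # band-pass: give every section one DC zero and one Nyquist zero so each
    # biquad is itself a moderate-gain band-pass; grouping like zeros
    # together creates sections with extreme gains whose edge transients
    # dominate the cascade
    zz <- lapply(seq_along(pp), function(i) {
      z <- complex(0)
      if (length(pos) >= i) z <- c(z, pos[i])
      if (length(neg) >= i) z <- c(z, neg[i])
      z
    })
  } else {
    zz <- pair_up(zeros)
  }
  # pad with zero-less sections if fewer zero groups than pole groups
  while (length(zz) < length(pp)) zz <- c(zz, list(complex(0)))
  sos <- lapply(seq_along(pp), function(i) {
    a <- poly_from_roots(pp[[i]])
    b <- poly_from_roots(zz[[i]])
    b <- c(b, rep(0, length(a) - length(b)))
    list(b = b / a[1], a = a / a[1])
  })
  h <- Reduce(`*`, lapply(sos, function(s)
    abs(freq_response(s$b, s$a, wref))))
  sos[[1]]$b <- sos[[1]]$b / h
  sos
}

#' Zero-phase filtering through cascaded second-order sections
#'
#' Applies [filtfilt()] section by section; numerically robust for
#' high-order or narrow-band designs whose single expanded polynomial would
#' have clustered roots.
#'
#' @param x numeric vector.
#' @param sos list of `list(b, a)` sections, as in the `sos` field of
#'   [butter_design()].
#' @param npad reflection pad length per pass (see [filtfilt()]).
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_sos <- function(x, sos, npad = NULL) {
  for (s in sos) x <- filtfilt(x, s$b, s$a, npad = npad)
  x
}

#' Second-order IIR notch filter
#'
#' Standard biquad notch at `f0` Hz with quality factor `Q`
#' (bandwidth `f0 / Q`); unit gain away from the notch, zero at `f0`.
#'
#' @param f0 notch frequency in Hz (must be below Nyquist).
#' @param fs sampling rate in Hz.
#' @param Q quality factor (default 30).
#' @return List with `b` and `a` coefficients.
#' @export
notch_design <- function(f0, fs, Q = 30) {
  if (f0 <= 0 || f0 >= fs / 2) stop("notch frequency must be in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Steady-state initial filter state for a unit step input (the classic
# lfilter_zi construction): scaling it by the first sample removes the
# start-up transient of each filtfilt pass.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  n <- nf - 1
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[2:nf] / a[1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  solve(diag(n) - t(comp), b[2:nf] - a[2:nf] * b[1])
}

iir_filter <- function(x, b, a, zi = NULL) {
  if (is.null(zi)) zi <- numeric(max(length(a), length(b)) - 1)
  iir_filter_cpp(as.numeric(x), b, a, zi)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and then backward so the net phase response is
#' zero; the amplitude response is applied twice. Edges are handled by
#' even (mirror) reflection padding plus steady-state initialisation of the
#' filter state on both passes. Even reflection is used deliberately: odd
#' reflection about an endpoint sitting at an oscillation extremum inserts a
#' DC plateau of twice the oscillation amplitude into the padding, which a
#' slow high-pass (0.1 Hz corner, ~4 s time constant) converts into a large
#' transient bleeding into the signal; mirroring preserves the local mean.
#'
#' @param x numeric vector.
#' @param b,a filter coefficients as from [butter_design()] or
#'   [notch_design()].
#' @param npad reflection pad length (samples) on each end.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(x, b, a, npad = NULL) {
  n <- length(x)
  if (n < 2) stop("signal too short to filter")
  nfilt <- max(length(a), length(b))
  if (is.null(npad)) npad <- min(n - 1, max(3 * (nfilt - 1), 50))
  npad <- min(npad, n - 1)
  ext <- c(x[(npad + 1):2], x, x[(n - 1):(n - npad)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(ext, b, a, zi * ext[1])
  y <- rev(y)
  y <- rev(iir_filter(y, b, a, zi * y[1]))
  y[(npad + 1):(npad + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' FFT-based analytic signal: the returned complex series has the input as
#' its real part, instantaneous envelope as its modulus and instantaneous
#' phase as its argument.
#'
#' @param x numeric vector.
#' @return Complex vector of the same length.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  if (n < 2) stop("signal too short for analytic representation")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}
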