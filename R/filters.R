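# Order-n Butterworth band-pass design (bilinear transform, second-order
# sections) and zero-phase forward-backward filtering. Implemented from the
# analog prototype because no IIR design routine ships with base R; sections
# are kept in biquad form for numerical stability at order 8.

#' Frequency band specification
#'
#' @param name band label (e.g. `"alpha"`)
#' @param lo lower edge in Hz, strictly positive
#' @param hi upper edge in Hz, greater than `lo`
#' @return an object of class `band_spec`
#' @export
#' @examples
#' band_spec("alpha", 8, 12)
band_spec <- function(name, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo)) {
    stopf("band '%s': need 0 < lo < hi (got lo=%s, hi=%s)", name, lo, hi)
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "band_spec")
}

#' The five standard EEG analysis bands
#'
#' Delta+theta (1-8 Hz), alpha (8-12), beta (12-35), gamma-1 (35-70) and
#' gamma-2 (70-100). Bands whose lower edge reaches the Nyquist limit of a
#' recording are dropped (with a warning) at extraction time.
#' @return list of [band_spec] objects
#' @export
default_bands <- function() {
  list(
    band_spec("delta_theta", 1, 8),
    band_spec("alpha", 8, 12),
    band_spec("beta", 12, 35),
    band_spec("gamma1", 35, 70),
    band_spec("gamma2", 70, 100)
  )
}

#' Design a stable Butterworth band-pass filter
#'
#' Analog Butterworth prototype, low-pass-to-band-pass transform, bilinear
#' transform with frequency pre-warping, factored into second-order sections.
#' The upper band edge is clipped to 0.99 x Nyquist; a band whose lower edge
#' survives no usable passband is rejected.
#'
#' @param band a [band_spec]
#' @param fs sampling rate in Hz
#' @param order prototype order of the band-pass design (default 8)
#' @return an object of class `bp_filter` with elements `sos` (n_sections x 6
#'   matrix of b0,b1,b2,a0,a1,a2), `gain`, `order`, `band`, `fs`
#' @export
design_bandpass <- function(band, fs, order = 8L) {
  stopifnot(inherits(band, "band_spec"), is.numeric(fs), fs > 0,
            is_count(order))
  nyq <- fs / 2
  hi <- min(band$hi, 0.99 * nyq)
  if (band$lo >= hi) {
    stopf("band '%s' (%g-%g Hz) lies at or above the usable range for fs=%g Hz (Nyquist %g Hz)",
          band$name, band$lo, band$hi, fs, nyq)
  }
  if (hi < band$hi) {
    message(sprintf("band '%s': upper edge clipped from %g to %g Hz (fs=%g)",
                    band$name, band$hi, hi, fs))
  }
  n <- as.integer(order)
  fs2 <- 2 * fs
  # pre-warp the digital edges onto the analog axis
  w1 <- fs2 * tan(pi * band$lo / fs)
  w2 <- fs2 * tan(pi * hi / fs)
  # analog low-pass prototype: n poles on the unit circle, left half plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # low-pass -> band-pass: each pole splits in two; n zeros appear at s = 0
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  ps <- p_lp * bw / 2
  disc <- sqrt(ps^2 - w0^2)
  p_bp <- c(ps + disc, ps - disc)
  k_bp <- bw^n
  # bilinear transform; the n zeros at s=0 map to z=1, the n-fold degree
  # deficit contributes n zeros at z=-1
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  k_z <- k_bp * Re(fs2^n / prod(fs2 - p_bp))
  sos <- pair_poles_to_sos(p_z)
  filt <- structure(list(sos = sos, gain = k_z, order = n,
                         band = band, fs = fs, hi_used = hi),
                    class = "bp_filter")
  if (max(Mod(p_z)) >= 1) {
    stopf("band '%s' at fs=%g Hz produced an unstable design", band$name, fs)
  }
  filt
}

# Pair the 2n band-pass poles into conjugate (or real) pairs; every section
# gets numerator (z-1)(z+1) = [1, 0, -1], i.e. one of the n zeros at +1 and
# one of the n at -1.
pair_poles_to_sos <- function(p) {
  tol <- 1e-8
  used <- rep(FALSE, length(p))
  secs <- list()
  ord <- order(Mod(p))  # least-peaked sections first
  for (i in ord) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(p[i])) > tol) {
      # find the conjugate partner
      j <- which(!used & abs(p - Conj(p[i])) < 1e-6 * (1 + Mod(p[i])))
      if (length(j) == 0L) {
        j <- which(!used & abs(Im(p) + Im(p[i])) ==
                     min(abs(Im(p)[!used] + Im(p[i]))))
      }
      j <- j[1L]
    } else {
      cand <- which(!used & abs(Im(p)) <= tol)
      if (length(cand) == 0L) stopf("unpaired real pole in band-pass design")
      j <- cand[which.min(abs(Re(p)[cand] - Re(p[i])))]
    }
    used[j] <- TRUE
    a1 <- -Re(p[i] + p[j])
    a2 <- Re(p[i] * p[j])
    secs[[length(secs) + 1L]] <- c(1, 0, -1, 1, a1, a2)
  }
  do.call(rbind, secs)
}

#' Complex frequency response of a band-pass design
#'
#' @param filt a `bp_filter`
#' @param f frequencies in Hz
#' @return complex vector `H(f)`; `Mod()` gives the single-pass magnitude
#' @export
filter_response <- function(filt, f) {
  stopifnot(inherits(filt, "bp_filter"))
  z1 <- exp(-2i * pi * f / filt$fs)
  H <- rep(complex(real = filt$gain), length(f))
  for (s in seq_len(nrow(filt$sos))) {
    b <- filt$sos[s, 1:3]
    a <- filt$sos[s, 4:6]
    H <- H * (b[1] + b[2] * z1 + b[3] * z1^2) /
      (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  H
}

# One biquad applied causally with steady-state initial conditions for a
# constant input equal to x[1] (suppresses the start-up transient; the same
# convention standard filtfilt implementations use).
biquad_filter <- function(b, a, x) {
  # direct form via filter(): FIR part vectorised, then the recursion
  n <- length(x)
  x_ext <- c(x[1], x[1], x)
  xb <- b[1] * x_ext[3:(n + 2)] + b[2] * x_ext[2:(n + 1)] + b[3] * x_ext[1:n]
  dc <- sum(b) / sum(a)
  y0 <- dc * x[1]
  as.numeric(stats::filter(xb, filter = -a[2:3], method = "recursive",
                           init = c(y0, y0)))
}

sos_filter_pass <- function(filt, x) {
  y <- x * filt$gain
  for (s in seq_len(nrow(filt$sos))) {
    y <- biquad_filter(filt$sos[s, 1:3], filt$sos[s, 4:6], y)
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the design forward and once reversed, so the effective magnitude
#' response is squared and the group delay cancels. Edges are handled by odd
#' reflection padding.
#'
#' @param signal numeric vector, longer than 3 x filter order
#' @param filt a `bp_filter` from [design_bandpass()]
#' @return filtered vector, same length as `signal`
#' @export
zero_phase_filter <- function(signal, filt) {
  stopifnot(inherits(filt, "bp_filter"))
  if (!is.numeric(signal) || anyNA(signal)) {
    stopf("signal must be numeric with no NA values")
  }
  n <- length(signal)
  if (n <= 3 * filt$order) {
    stopf("signal too short for zero-phase filtering: length %d <= 3 x order %d",
          n, filt$order)
  }
  padlen <- min(3L * (2L * nrow(filt$sos) + 1L), n - 1L)
  pre <- 2 * signal[1] - signal[(padlen + 1):2]
  post <- 2 * signal[n] - signal[(n - 1):(n - padlen)]
  x <- c(pre, signal, post)
  y <- sos_filter_pass(filt, x)
  y <- rev(sos_filter_pass(filt, rev(y)))
  y[(padlen + 1):(padlen + n)]
}
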