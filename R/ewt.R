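#' Single-channel signal
#'
#' Light container for a uniformly sampled real time series.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units, e.g. uV).
#' @param rate Sampling rate in Hz.
#' @return An object of class `"fewt_signal"` with elements `samples` and
#'   `rate`.
#' @examples
#' s <- signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), rate = 250)
#' @export
signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  stopifnot_scalar_number(rate, "rate", positive = TRUE)
  if (length(samples) < 2L) stop("signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples))) stop("signal samples must be finite", call. = FALSE)
  structure(list(samples = samples, rate = rate), class = "fewt_signal")
}

as_signal <- function(x, rate = NULL) {
  if (inherits(x, "fewt_signal")) return(x)
  if (is.null(rate)) stop("`rate` required when input is a bare vector", call. = FALSE)
  signal(x, rate)
}

#' Spectrum segmentation
#'
#' Fourier-support boundaries on the normalized angular frequency axis
#' `[0, pi]` plus the transition half-widths of the internal boundaries.
#' Segment `n` is `[omega_{n-1}, omega_n]`; each internal boundary `omega_n`
#' carries a transition zone of width `2 * tau_n` centred on it, and the
#' non-overlap requirement `tau_n < min(adjacent gaps) / 2` guarantees the
#' wavelet case ranges partition the axis.
#'
#' @param boundaries Increasing numeric vector `omega_0 .. omega_N` with
#'   `omega_0 = 0`, `omega_N = pi`.
#' @param halfwidths Numeric vector `tau_1 .. tau_{N-1}` for the internal
#'   boundaries only (length 0 when `N = 1`).
#' @return An object of class `"fewt_segmentation"`.
#' @export
spectrum_segmentation <- function(boundaries, halfwidths = numeric(0)) {
  boundaries <- as.numeric(boundaries)
  halfwidths <- as.numeric(halfwidths)
  N <- length(boundaries) - 1L
  if (N < 1L) stop("segmentation needs at least boundaries {0, pi}", call. = FALSE)
  if (abs(boundaries[1L]) > 1e-12 || abs(boundaries[N + 1L] - pi) > 1e-9) {
    stop("boundaries must start at 0 and end at pi", call. = FALSE)
  }
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  if (length(halfwidths) != max(N - 1L, 0L)) {
    stop("need one halfwidth per internal boundary", call. = FALSE)
  }
  seg <- structure(
    list(boundaries = boundaries, halfwidths = halfwidths, n_segments = N),
    class = "fewt_segmentation"
  )
  validate_segmentation(seg)
  seg
}

validate_segmentation <- function(seg) {
  b <- seg$boundaries
  tau <- seg$halfwidths
  N <- seg$n_segments
  if (N == 1L) return(invisible(seg))
  gaps <- diff(b)
  for (n in seq_len(N - 1L)) {
    bound <- min(gaps[n], gaps[n + 1L]) / 2
    if (tau[n] <= 0 || tau[n] >= bound) {
      stop(sprintf(
        "transition halfwidth tau_%d = %.6g violates non-overlap bound %.6g at boundary omega_%d = %.6g",
        n, tau[n], bound, n, b[n + 1L]
      ), call. = FALSE)
    }
  }
  invisible(seg)
}

#' Meyer transition polynomial
#'
#' `beta(x) = x^4 (35 - 84 x + 70 x^2 - 20 x^3)`, clamped so that
#' `beta(x) = 0` for `x <= 0` and `1` for `x >= 1`. Satisfies
#' `beta(x) + beta(1 - x) = 1`, which the tight-frame identity of the filter
#' bank requires.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
meyer_beta <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

#' Detect Fourier-support boundaries from a magnitude spectrum
#'
#' Places the internal boundaries at midpoints between the `n_supports`
#' largest local maxima of the magnitude spectrum (ties broken towards lower
#' frequency). Transition half-widths are `gamma * omega_n`, clipped to the
#' non-overlap bound. When the spectrum carries fewer distinct local maxima
#' than requested the function falls back to an equal-width segmentation of
#' `[0, pi]` and logs a note, so batch encoding never aborts on a quiet
#' window.
#'
#' @param spectrum_magnitude Non-negative magnitudes sampled uniformly on
#'   `[0, pi]` (e.g. the positive-frequency half of an FFT modulus).
#' @param n_supports Number of segments `N >= 1`.
#' @param gamma Relative transition half-width in `(0, 1)`; default `0.1`.
#' @return A [spectrum_segmentation()].
#' @export
detect_boundaries <- function(spectrum_magnitude, n_supports, gamma = 0.1) {
  mag <- as.numeric(spectrum_magnitude)
  if (any(!is.finite(mag)) || any(mag < 0)) {
    stop("spectrum magnitudes must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(n_supports) || n_supports < 1) {
    stop("`n_supports` must be a positive integer", call. = FALSE)
  }
  n_supports <- as.integer(n_supports)
  if (gamma <= 0 || gamma >= 1) stop("`gamma` must lie in (0, 1)", call. = FALSE)
  L <- length(mag)
  if (L < 2L * n_supports) {
    stop("spectrum too short for the requested number of supports", call. = FALSE)
  }
  if (n_supports == 1L) {
    return(spectrum_segmentation(c(0, pi)))
  }
  omega_grid <- pi * (seq_len(L) - 1) / (L - 1)

  # interior local maxima, strictly above both neighbours
  interior <- 2:(L - 1L)
  is_peak <- mag[interior] > mag[interior - 1L] & mag[interior] > mag[interior + 1L]
  peaks <- interior[is_peak]

  if (length(peaks) < n_supports - 0L) {
    # need n_supports peaks to delimit n_supports segments by midpoints
    fewt_log(sprintf(
      "only %d local maxima for %d supports; falling back to equal-width segmentation",
      length(peaks), n_supports
    ))
    boundaries <- seq(0, pi, length.out = n_supports + 1L)
  } else {
    ord <- order(-mag[peaks], peaks)
    top <- sort(peaks[ord[seq_len(n_supports)]])
    mids <- (omega_grid[top[-length(top)]] + omega_grid[top[-1L]]) / 2
    boundaries <- c(0, mids, pi)
  }

  gaps <- diff(boundaries)
  N <- n_supports
  tau <- numeric(N - 1L)
  for (n in seq_len(N - 1L)) {
    bound <- min(gaps[n], gaps[n + 1L]) / 2
    tau[n] <- min(gamma * boundaries[n + 1L], bound * (1 - 1e-9))
  }
  spectrum_segmentation(boundaries, tau)
}

#' Build the empirical wavelet filter bank
#'
#' Evaluates the empirical scaling function and wavelets on the discrete FFT
#' grid, mirrored for negative frequencies (all filters are even in omega).
#' The low-pass scaling filter is 1 below the first internal boundary's
#' transition and rolls off as `cos(pi/2 * beta(.))`; each bandpass wavelet
#' rises as `sin(pi/2 * beta(.))` through its lower transition, is 1 on the
#' passband, and falls as `cos(pi/2 * beta(.))` through its upper one. With
#' the Meyer polynomial the bank is a tight frame:
#' `phi1^2 + sum_n psi_n^2 = 1` at every grid point.
#'
#' @param seg A [spectrum_segmentation()] satisfying its invariants.
#' @param fft_length Length of the FFT grid (the signal length), `>= 4`.
#' @return An object of class `"fewt_bank"` with elements `grid` (the folded
#'   absolute normalized angular frequency per FFT bin), `scaling`,
#'   `wavelets` (list, possibly empty), `segmentation`, `beta_kind`.
#' @export
build_filter_bank <- function(seg, fft_length) {
  if (!inherits(seg, "fewt_segmentation")) stop("`seg` must be a segmentation", call. = FALSE)
  validate_segmentation(seg)
  fft_length <- as.integer(fft_length)
  if (fft_length < 4L) stop("`fft_length` must be at least 4", call. = FALSE)

  k <- 0:(fft_length - 1L)
  w <- 2 * pi * k / fft_length
  wa <- pmin(w, 2 * pi - w)  # fold: |omega| in [0, pi]

  b <- seg$boundaries
  tau <- seg$halfwidths
  N <- seg$n_segments

  if (N == 1L) {
    scaling <- rep(1, fft_length)
    wavelets <- list()
  } else {
    w1 <- b[2L]; t1 <- tau[1L]
    scaling <- numeric(fft_length)
    scaling[wa <= w1 - t1] <- 1
    tz <- wa > w1 - t1 & wa <= w1 + t1
    scaling[tz] <- cos(pi / 2 * meyer_beta((wa[tz] - w1 + t1) / (2 * t1)))

    wavelets <- vector("list", N - 1L)
    for (n in seq_len(N - 1L)) {
      wn <- b[n + 1L]; tn <- tau[n]
      psi <- numeric(fft_length)
      lower <- wa >= wn - tn & wa <= wn + tn
      psi[lower] <- sin(pi / 2 * meyer_beta((wa[lower] - wn + tn) / (2 * tn)))
      if (n < N - 1L) {
        wn1 <- b[n + 2L]; tn1 <- tau[n + 1L]
        psi[wa > wn + tn & wa < wn1 - tn1] <- 1
        upper <- wa >= wn1 - tn1 & wa <= wn1 + tn1
        psi[upper] <- cos(pi / 2 * meyer_beta((wa[upper] - wn1 + tn1) / (2 * tn1)))
      } else {
        psi[wa > wn + tn] <- 1  # last band extends to the Nyquist edge
      }
      wavelets[[n]] <- psi
    }
  }
  structure(
    list(
      grid = wa, scaling = scaling, wavelets = wavelets,
      segmentation = seg, beta_kind = "meyer"
    ),
    class = "fewt_bank"
  )
}

bank_filters <- function(bank) {
  c(list(bank$scaling), bank$wavelets)
}

#' Empirical wavelet transform
#'
#' Forward transform: each component is the inverse FFT of the signal
#' spectrum multiplied by the (real, even) conjugated filter, so components
#' are real up to round-off.
#'
#' @param sig A [signal()] (or numeric vector with `rate` given through
#'   `...` in helpers).
#' @param bank A [build_filter_bank()] result whose grid length equals the
#'   signal length.
#' @return Object of class `"fewt_decomposition"`: `approx` (low-pass
#'   component), `details` (list of band components), `bank`, `rate`.
#' @export
ewt_decompose <- function(sig, bank) {
  sig <- as_signal(sig)
  x <- sig$samples
  n <- length(x)
  if (!inherits(bank, "fewt_bank")) stop("`bank` must be a filter bank", call. = FALSE)
  if (length(bank$grid) != n) {
    stop(sprintf(
      "signal length %d does not match bank grid length %d", n, length(bank$grid)
    ), call. = FALSE)
  }
  X <- stats::fft(x)
  comps <- lapply(bank_filters(bank), function(filt) {
    y <- stats::fft(X * Conj(filt), inverse = TRUE) / n
    res <- max(abs(Im(y)))
    nrm <- sqrt(sum(x^2))
    if (nrm > 0 && res > 1e-9 * nrm) {
      stop("non-negligible imaginary residue in EWT component", call. = FALSE)
    }
    Re(y)
  })
  structure(
    list(approx = comps[[1L]], details = comps[-1L], bank = bank, rate = sig$rate),
    class = "fewt_decomposition"
  )
}

#' Inverse empirical wavelet transform
#'
#' Reconstructs the signal as the sum of each coefficient series filtered
#' once more by its own (real) filter in the spectral domain; the tight-frame
#' identity makes the round trip exact to round-off.
#'
#' @param dec A `"fewt_decomposition"`.
#' @return A [signal()].
#' @export
ewt_reconstruct <- function(dec) {
  if (!inherits(dec, "fewt_decomposition")) {
    stop("`dec` must be an EWT decomposition", call. = FALSE)
  }
  if (is.null(dec$bank)) stop("decomposition carries no filter bank", call. = FALSE)
  comps <- c(list(dec$approx), dec$details)
  filters <- bank_filters(dec$bank)
  n <- length(comps[[1L]])
  acc <- complex(n)
  for (i in seq_along(comps)) {
    acc <- acc + stats::fft(comps[[i]]) * filters[[i]]
  }
  signal(Re(stats::fft(acc, inverse = TRUE) / n), rate = dec$rate %||% 1)
}
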