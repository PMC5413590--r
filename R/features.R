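#' Encoding configuration
#'
#' Collects the tunables of the FEWT encoder in one list. `supports` is the
#' number of EWT segments (and FCM clusters) per channel; `gamma` the
#' relative transition half-width of the wavelet bank; `entropy_bins` the
#' amplitude-histogram resolution of the Shannon-entropy descriptor;
#' `refine` switches the fuzzy band refinement on (FEWT) or off (plain EWT
#' band components). The `fcm` sub-list carries the clustering controls,
#' including `restarts` seeded restarts whose lowest-objective fit is kept.
#'
#' @param supports Number of frequency bands per channel (default 3).
#' @param gamma Transition half-width factor in `(0, 1)` (default 0.1).
#' @param entropy_bins Histogram bins for the entropy descriptor (default 16).
#' @param refine Logical; apply the FCM band refinement (default `TRUE`).
#' @param fcm List of FCM controls: `m`, `tol`, `max_iter`, `restarts`,
#'   `seed`.
#' @return A list of class `"fewt_config"`.
#' @export
fewt_config <- function(supports = 3L, gamma = 0.1, entropy_bins = 16L,
                        refine = TRUE,
                        fcm = list()) {
  fc <- utils::modifyList(
    list(m = 2, tol = 1e-6, max_iter = 300L, restarts = 5L, seed = 1L),
    fcm
  )
  structure(
    list(
      supports = as.integer(supports), gamma = gamma,
      entropy_bins = as.integer(entropy_bins), refine = isTRUE(refine),
      fcm = fc
    ),
    class = "fewt_config"
  )
}

#' Refine EWT supports into non-overlapping frequency bands
#'
#' The empirical wavelet supports of a multicomponent signal can overlap in
#' practice (chirps crossing in time and frequency); this step re-assigns
#' every positive-frequency bin to exactly one of `c` bands by fuzzy
#' c-means. The spectral mass is clustered along the frequency axis:
#' power-weighted FCM on the bin frequencies (each bin weighted by its
#' spectral power), so cluster centroids settle where the signal's energy
#' concentrates. Each bin goes to its maximum-membership cluster — in one
#' dimension a Voronoi partition, hence always contiguous frequency bands —
#' and clusters are relabelled 1..c by ascending centroid frequency. Band
#' components are inverse transforms of the spectrum masked to each band's
#' bins (conjugate-symmetric completion), so the bands partition the
#' frequency axis and sum to the signal exactly.
#'
#' The DC bin (and nothing else) is attached to band 1 so the partition
#' covers the whole grid. A spectrum with (numerically) zero total power is
#' clustered with uniform weights, which yields equal-width bands.
#'
#' @param sig A [signal()].
#' @param dec The signal's EWT decomposition (supplies the default number of
#'   bands; the refinement itself reclusters the spectrum).
#' @param c Number of bands; defaults to the decomposition's segment count.
#' @param config A [fewt_config()] (its `fcm` entry is used).
#' @return Object of class `"fewt_bands"`: `bin_to_band` (one label per FFT
#'   bin of the positive half, DC included), `band_components` (list of `c`
#'   real series), `c`.
#' @export
refine_bands <- function(sig, dec = NULL, c = NULL, config = fewt_config()) {
  sig <- as_signal(sig)
  x <- sig$samples
  n <- length(x)
  if (is.null(c)) {
    if (is.null(dec)) stop("give `c` or a decomposition", call. = FALSE)
    c <- dec$bank$segmentation$n_segments
  }
  c <- as.integer(c)
  nyq <- n %/% 2L                    # bins 1..nyq are the positive frequencies
  if (c < 1L) stop("`c` must be at least 1", call. = FALSE)
  if (c >= nyq) stop("`c` must be smaller than the number of positive bins", call. = FALSE)

  X <- stats::fft(x)
  pos <- 2:(nyq + 1L)                # R indices of positive-frequency bins
  if (c == 1L) {
    assign_pos <- rep(1L, length(pos))
  } else {
    freq <- (pos - 1) / n                       # normalized frequency
    pw <- Mod(X[pos])^2
    if (sum(pw) <= 0) {
      fewt_log("zero-power spectrum: refining with uniform bin weights")
      pw <- rep(1, length(pos))
    }

    best <- NULL
    fc <- config$fcm
    for (r in seq_len(fc$restarts)) {
      fit <- fcm_fit(freq, c = c, m = fc$m, tol = fc$tol,
                     max_iter = fc$max_iter,
                     seed = child_seed(fc$seed, r), weights = pw)
      obj <- fit$objective_trace[length(fit$objective_trace)]
      if (is.null(best) || obj < best$obj) best <- list(fit = fit, obj = obj)
    }
    fit <- best$fit
    relabel <- order(fit$centroids[, 1L])       # ascending centroid frequency
    hard <- apply(fit$memberships, 2L, which.max)
    assign_pos <- match(hard, relabel)
  }

  band_components <- vector("list", c)
  full_assign <- integer(n)
  full_assign[1L] <- 1L                         # DC with the lowest band
  full_assign[pos] <- assign_pos
  neg <- setdiff(seq_len(n), c(1L, pos))        # mirror bins
  if (length(neg)) full_assign[neg] <- full_assign[n - neg + 2L]
  for (b in seq_len(c)) {
    mask <- as.numeric(full_assign == b)
    band_components[[b]] <- Re(stats::fft(X * mask, inverse = TRUE) / n)
  }
  structure(
    list(bin_to_band = full_assign[c(1L, pos)], band_components = band_components,
         c = c, rate = sig$rate),
    class = "fewt_bands"
  )
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' Counts the phrases of the LZ76 exhaustive-history parsing
#' (Kaspar-Schuster scan) and, when `normalize = TRUE`, divides by the
#' asymptotic random-sequence rate `n / log2(n)`.
#'
#' @param bits Integer/logical vector of 0s and 1s, length >= 2.
#' @param normalize Logical (default `TRUE`).
#' @return A single number.
#' @export
lz76_complexity <- function(bits, normalize = TRUE) {
  s <- as.integer(as.logical(bits))
  n <- length(s)
  if (n < 2L) stop("sequence too short", call. = FALSE)
  cn <- 1L; l <- 1L; i <- 0L; k <- 1L; kmax <- 1L
  repeat {
    if (s[i + k] != s[l + k]) {
      if (k > kmax) kmax <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + kmax
        if (l + 1L > n) break
        i <- 0L; k <- 1L; kmax <- 1L
      } else {
        k <- 1L
      }
    } else {
      k <- k + 1L
      if (l + k > n) {
        cn <- cn + 1L
        break
      }
    }
  }
  if (normalize) cn / (n / log2(n)) else as.numeric(cn)
}

#' Eight-parameter statistical descriptor of a band component
#'
#' Computes root mean square, normalized LZ76 complexity of the
#' median-binarized series, Shannon entropy of a `entropy_bins`-bin
#' amplitude histogram (base-2, empty bins skipped), power-spectrum centroid
#' (central frequency, Hz), frequency of the largest power-spectrum bin
#' (maximum frequency, Hz), unbiased variance, and the uncorrected moment
#' ratios skewness `m3 / m2^(3/2)` and kurtosis `m4 / m2^2`. A constant
#' band yields variance 0 and, by convention, skewness, kurtosis and entropy
#' 0 (logged once per call).
#'
#' @param band Numeric vector, length >= 8.
#' @param rate Sampling rate in Hz.
#' @param entropy_bins Number of amplitude histogram bins (default 16).
#' @return Named numeric vector of the eight descriptors, in the canonical
#'   order `rms, lz, entropy, cfreq, maxfreq, var, skew, kurt`.
#' @export
compute_descriptors <- function(band, rate, entropy_bins = 16L) {
  x <- as.numeric(band)
  n <- length(x)
  if (n < 8L) stop("band must hold at least 8 samples", call. = FALSE)
  stopifnot_scalar_number(rate, "rate", positive = TRUE)

  rms <- sqrt(mean(x^2))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    fewt_log("constant band component: variance, skewness, kurtosis, entropy set to 0")
    skew <- 0; kurt <- 0; entropy <- 0; varx <- 0
  } else {
    m3 <- mean((x - m)^3)
    m4 <- mean((x - m)^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
    varx <- stats::var(x)
    breaks <- seq(min(x), max(x), length.out = entropy_bins + 1L)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = entropy_bins)
    pr <- counts[counts > 0] / n
    entropy <- -sum(pr * log2(pr))
  }

  nyq <- n %/% 2L
  P <- Mod(stats::fft(x)[1:(nyq + 1L)])^2
  f <- (0:nyq) * rate / n
  tot <- sum(P)
  cfreq <- if (tot > 0) sum(f * P) / tot else 0
  maxfreq <- f[which.max(P)]

  lz <- lz76_complexity(x > stats::median(x))

  c(rms = rms, lz = lz, entropy = entropy, cfreq = cfreq,
    maxfreq = maxfreq, var = varx, skew = skew, kurt = kurt)
}

descriptor_names <- c("rms", "lz", "entropy", "cfreq", "maxfreq",
                      "var", "skew", "kurt")

#' Encode one multi-channel window into a feature row
#'
#' Per channel: detect Fourier supports, build the empirical wavelet bank,
#' decompose, optionally refine the supports into non-overlapping bands by
#' fuzzy c-means (`config$refine`), and describe each band with the eight
#' statistical parameters. Blocks are concatenated channel-major (channel 1
#' band 1 params 1-8, channel 1 band 2, ...), giving
#' `channels x supports x 8` values — 144 for the default 6-channel,
#' 3-support setup.
#'
#' @param window Numeric matrix, samples x channels, or a [signal()] for a
#'   single channel.
#' @param rate Sampling rate in Hz.
#' @param config A [fewt_config()].
#' @return Named numeric feature row.
#' @export
encode_window <- function(window, rate, config = fewt_config()) {
  if (inherits(window, "fewt_signal")) {
    rate <- window$rate
    window <- matrix(window$samples, ncol = 1L)
  }
  window <- as.matrix(window)
  n <- nrow(window)
  min_len <- max(8L, 4L * config$supports)
  row <- numeric(0)
  for (ch in seq_len(ncol(window))) {
    if (n < min_len) {
      stop(sprintf("channel %d too short (%d samples) for %d supports",
                   ch, n, config$supports), call. = FALSE)
    }
    sig <- signal(window[, ch], rate)
    mag <- Mod(stats::fft(sig$samples))[1:(n %/% 2L + 1L)]
    seg <- detect_boundaries(mag, config$supports, config$gamma)
    bank <- build_filter_bank(seg, n)
    dec <- ewt_decompose(sig, bank)
    comps <- if (config$refine) {
      refine_bands(sig, dec, c = config$supports, config = config)$band_components
    } else {
      c(list(dec$approx), dec$details)
    }
    for (b in seq_along(comps)) {
      row <- c(row, compute_descriptors(comps[[b]], rate, config$entropy_bins))
    }
  }
  names(row) <- as.vector(outer(
    descriptor_names,
    as.vector(outer(seq_len(config$supports), seq_len(ncol(window)),
                    function(b, ch) sprintf("ch%d.b%d", ch, b))),
    function(p, cb) paste(cb, p, sep = ".")
  ))
  row
}

#' Feature matrix container
#'
#' @param x Numeric matrix, one row per window.
#' @param labels Class label per row.
#' @param meta Optional data frame of per-row metadata (trial, window,
#'   subject).
#' @return Object of class `"fewt_features"`.
#' @export
feature_matrix <- function(x, labels, meta = NULL) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x)) stop("one label per row required", call. = FALSE)
  if (!all(is.finite(x))) stop("feature matrix entries must be finite", call. = FALSE)
  structure(list(x = x, labels = as.character(labels), meta = meta),
            class = "fewt_features")
}

#' Encode a trial set into a feature matrix
#'
#' Splits every trial into non-overlapping windows and encodes each window
#' with [encode_window()].
#'
#' @param trials A trial set from [gen_trials()] or [read_trials()].
#' @param window_seconds Window length in seconds (default 0.5).
#' @param config A [fewt_config()].
#' @return A [feature_matrix()].
#' @export
encode_trials <- function(trials, window_seconds = 0.5, config = fewt_config()) {
  wins <- segment_trials(trials, window_seconds)
  rows <- lapply(wins, function(w) encode_window(w$data, trials$rate, config))
  x <- do.call(rbind, rows)
  meta <- data.frame(
    trial = vapply(wins, `[[`, integer(1), "trial"),
    window = vapply(wins, `[[`, integer(1), "window"),
    subject = vapply(wins, `[[`, character(1), "subject"),
    stringsAsFactors = FALSE
  )
  feature_matrix(x, vapply(wins, `[[`, character(1), "label"), meta)
}
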