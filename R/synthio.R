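#' Multicomponent AM-FM test signal
#'
#' Sum of amplitude- and frequency-modulated cosines
#' `a_j(t) cos(2 pi (f_j t + c_j t^2 / 2) + phi_j)` with
#' `a_j(t) = amp_j (1 + 0.5 sin(2 pi am_j t))`, plus optional Gaussian
#' noise. Component phases are drawn under the seed, so the generator is
#' deterministic per seed and can place several chirps overlapping in both
#' time and frequency — the failure mode the fuzzy band refinement exists
#' for.
#'
#' @param components List of component specs; each a list with `freq`
#'   (center frequency, Hz), and optional `am` (AM rate, Hz, default 0),
#'   `chirp` (chirp rate, Hz/s, default 0), `amp` (default 1).
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return A [signal()].
#' @export
gen_amfm <- function(components, duration, rate, noise_sd = 0, seed = 1L) {
  n <- as.integer(round(duration * rate))
  if (n < 64L) stop("duration * rate must be at least 64 samples", call. = FALSE)
  tt <- (0:(n - 1L)) / rate
  with_seed(seed, {
    phases <- stats::runif(length(components), 0, 2 * pi)
    x <- numeric(n)
    for (j in seq_along(components)) {
      cmp <- components[[j]]
      f <- cmp$freq
      if (is.null(f) || f >= rate / 2) stop("component frequency must be below Nyquist", call. = FALSE)
      am <- cmp$am %||% 0
      ch <- cmp$chirp %||% 0
      amp <- cmp$amp %||% 1
      a <- amp * (1 + 0.5 * sin(2 * pi * am * tt))
      x <- x + a * cos(2 * pi * (f * tt + 0.5 * ch * tt^2) + phases[j])
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
    signal(x, rate)
  })
}

# 1/f-shaped ("pink") background noise, unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k)          # folded bin index; 0 at DC
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(W * scale, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Band-limited unit-variance noise on [lo, hi] Hz.
band_noise <- function(n, rate, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * rate / n
  mask <- as.numeric(f >= lo & f <= hi)
  x <- Re(stats::fft(W * mask, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) stop("band mask captured no FFT bins", call. = FALSE)
  x / s
}

#' Trial set container
#'
#' @param trials List of trials; each a list with `data` (samples x
#'   channels numeric matrix), `label`, `subject`.
#' @param rate Sampling rate in Hz.
#' @return Object of class `"fewt_trialset"`.
#' @export
trial_set <- function(trials, rate) {
  stopifnot_scalar_number(rate, "rate", positive = TRUE)
  nch <- unique(vapply(trials, function(t) ncol(t$data), integer(1)))
  if (length(nch) != 1L) stop("all trials must share one channel count", call. = FALSE)
  structure(list(trials = trials, rate = rate, channels = nch),
            class = "fewt_trialset")
}

#' Generate EEG-like labeled two-class trials
#'
#' Each channel carries unit-variance 1/f-shaped background noise. On the
#' planted channels a band-limited component is added whose amplitude
#' differs between the two classes so that its *power* differs by the given
#' ratio (class 1 amplitude `effect_amp`, class 2 amplitude
#' `effect_amp * sqrt(ratio)`). Classes are exactly balanced and the whole
#' set is deterministic per seed. Defaults emulate a 6-channel, 250 Hz,
#' 10 s recording geometry (2500 samples per trial and channel).
#'
#' @param channels Number of channels (default 6).
#' @param rate Sampling rate in Hz (default 250).
#' @param duration Trial duration in seconds (default 10).
#' @param classes Two class labels.
#' @param planted List of planted effects; each a list with `channel`,
#'   `band` (`c(lo, hi)` in Hz), `ratio` (between-class power ratio > 0).
#' @param trials_per_class Trials per class (default 50).
#' @param effect_amp Class-1 amplitude of the planted band component
#'   relative to the unit background (default 0.5).
#' @param subject Subject id stored on every trial.
#' @param seed Integer seed.
#' @return A [trial_set()].
#' @export
gen_trials <- function(channels = 6L, rate = 250, duration = 10,
                       classes = c("task1", "task2"),
                       planted = list(list(channel = 2L, band = c(8, 12), ratio = 4)),
                       trials_per_class = 50L, effect_amp = 0.5,
                       subject = "s1", seed = 1L) {
  channels <- as.integer(channels)
  n <- as.integer(round(duration * rate))
  if (length(classes) != 2L) stop("exactly two class labels required", call. = FALSE)
  for (p in planted) {
    if (p$ratio <= 0) stop("planted power ratio must be positive", call. = FALSE)
    if (p$channel < 1L || p$channel > channels) {
      stop("planted channel outside channel count", call. = FALSE)
    }
  }
  plant_by_ch <- vector("list", channels)
  for (p in planted) plant_by_ch[[p$channel]] <- p

  with_seed(seed, {
    trials <- list()
    for (cls_i in 1:2) {
      for (tr in seq_len(trials_per_class)) {
        dat <- matrix(0, n, channels)
        for (ch in seq_len(channels)) {
          x <- pink_noise(n)
          p <- plant_by_ch[[ch]]
          if (!is.null(p)) {
            amp <- effect_amp * if (cls_i == 2L) sqrt(p$ratio) else 1
            x <- x + amp * band_noise(n, rate, p$band[1L], p$band[2L])
          }
          dat[, ch] <- x
        }
        trials[[length(trials) + 1L]] <- list(
          data = dat, label = classes[cls_i], subject = subject
        )
      }
    }
    trial_set(trials, rate)
  })
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a trial set as delimited text
#'
#' One tab-separated file per trial (`trial_0001.tsv`, columns `ch1..chK`)
#' plus a plain-text sidecar (`trial_0001.meta`) with `rate`, `label`,
#' `subject` as `key: value` lines. Numeric content round-trips at full
#' double precision.
#'
#' @param trials A `"fewt_trialset"`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written trial file paths.
#' @export
write_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "fewt_trialset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(trials$trials)) {
    tr <- trials$trials[[i]]
    stem <- file.path(dir, sprintf("trial_%04d", i))
    m <- apply(tr$data, 2L, fmt_num)
    colnames(m) <- paste0("ch", seq_len(ncol(tr$data)))
    utils::write.table(m, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(
      c(sprintf("rate: %s", fmt_num(trials$rate)),
        sprintf("label: %s", tr$label),
        sprintf("subject: %s", tr$subject)),
      paste0(stem, ".meta")
    )
    paths <- c(paths, paste0(stem, ".tsv"))
  }
  invisible(paths)
}

read_meta <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  out <- stats::setNames(
    vapply(kv, function(x) paste(x[-1L], collapse = ": "), character(1)),
    vapply(kv, `[[`, character(1), 1L)
  )
  as.list(out)
}

#' @rdname write_trials
#' @param dir Directory holding `trial_*.tsv` + `.meta` pairs.
#' @export
read_trials <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trial_.*\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no trial files found", call. = FALSE)
  rate <- NULL
  nch <- NULL
  trials <- list()
  for (f in files) {
    tab <- utils::read.table(f, header = TRUE, sep = "\t",
                             colClasses = "numeric", check.names = FALSE)
    expected <- paste0("ch", seq_len(ncol(tab)))
    unknown <- setdiff(names(tab), expected)
    if (length(unknown)) {
      stop(sprintf("unknown columns in %s: %s", basename(f),
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    meta <- read_meta(sub("\\.tsv$", ".meta", f))
    r <- as.numeric(meta$rate)
    if (is.null(rate)) rate <- r
    if (abs(r - rate) > 1e-9) stop(sprintf("rate mismatch in %s", basename(f)), call. = FALSE)
    if (is.null(nch)) nch <- ncol(tab)
    if (ncol(tab) != nch) {
      stop(sprintf("channel count mismatch in %s: %d vs %d",
                   basename(f), ncol(tab), nch), call. = FALSE)
    }
    trials[[length(trials) + 1L]] <- list(
      data = as.matrix(tab), label = meta$label, subject = meta$subject %||% "s1"
    )
  }
  trial_set(trials, rate)
}

#' Write / read a feature matrix as tab-separated text
#'
#' Header row of column names, a `label` column, and the metadata columns
#' (`trial`, `window`, `subject`) when present; numeric values at full
#' double precision.
#'
#' @param features A [feature_matrix()].
#' @param path Output file path.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "fewt_features"))
  num <- apply(features$x, 2L, fmt_num)
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(features$x))
  colnames(num) <- colnames(features$x)
  df <- data.frame(label = features$labels, stringsAsFactors = FALSE)
  if (!is.null(features$meta)) df <- cbind(df, features$meta)
  out <- cbind(df, num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("trial", "window", "subject"), names(tab))
  feat_cols <- setdiff(names(tab), c("label", meta_cols))
  x <- as.matrix(tab[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  meta <- if (length(meta_cols)) tab[, meta_cols, drop = FALSE] else NULL
  feature_matrix(x, tab$label, meta)
}
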