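test_that("boundary detection places midpoints between the largest spectral peaks", {
  n <- 1024; rate <- 250
  t <- (0:(n - 1)) / rate
  x <- cos(2 * pi * 20 * t) + cos(2 * pi * 80 * t)
  mag <- pos_magnitude(x)
  seg <- detect_boundaries(mag, 2, gamma = 0.1)

  # independent brute-force peak scan + midpoint on the discrete grid
  L <- length(mag)
  omega <- pi * (0:(L - 1)) / (L - 1)
  peaks <- which(mag[2:(L - 1)] > mag[1:(L - 2)] & mag[2:(L - 1)] > mag[3:L]) + 1L
  top2 <- sort(peaks[order(-mag[peaks])][1:2])
  expect_equal(seg$boundaries, c(0, mean(omega[top2]), pi))
  expect_length(seg$halfwidths, 1L)
  expect_lt(seg$halfwidths, min(diff(seg$boundaries)) / 2)
})

test_that("degenerate and fallback segmentations follow the stated rules", {
  mag <- runif(64)
  expect_equal(detect_boundaries(mag, 1)$boundaries, c(0, pi))
  expect_length(detect_boundaries(mag, 1)$halfwidths, 0L)

  flat <- rep(1, 128)
  expect_message(seg <- detect_boundaries(flat, 3), "equal-width")
  expect_equal(seg$boundaries, seq(0, pi, length.out = 4))

  expect_error(detect_boundaries(mag, 0), "positive")
  expect_error(detect_boundaries(c(1, 2), 3), "too short")
})

test_that("filter bank matches the closed-form transition values", {
  w1 <- 2 * pi * 200 / 2048                 # boundary placed exactly on-grid
  seg <- spectrum_segmentation(c(0, w1, 2, pi), c(0.1, 0.15))
  bank <- build_filter_bank(seg, 2048)

  expect_equal(bank$scaling[1L], 1)                   # phi(0) = 1
  expect_equal(meyer_beta(0.5), 0.5)
  # value at the first boundary center: cos(pi/2 * beta(1/2)) = cos(pi/4)
  expect_equal(bank$scaling[201L], cos(pi / 4))
  expect_true(all(vapply(c(list(bank$scaling), bank$wavelets),
                         function(f) all(f >= 0 & f <= 1 + 1e-12), logical(1))))
})

test_that("tight-frame identity holds on random admissible segmentations", {
  set.seed(101)
  for (i in 1:25) {
    N <- sample(2:6, 1)
    b <- sort(runif(N - 1, 0.2, pi - 0.2))
    while (any(diff(c(0, b, pi)) < 0.1)) b <- sort(runif(N - 1, 0.2, pi - 0.2))
    gaps <- diff(c(0, b, pi))
    tau <- vapply(seq_len(N - 1), function(n) {
      0.8 * min(gaps[n], gaps[n + 1]) / 2
    }, numeric(1))
    bank <- build_filter_bank(spectrum_segmentation(c(0, b, pi), tau), 512)
    expect_lt(max(abs(partition_of_unity(bank) - 1)), 1e-10)
  }
})

test_that("segmentation violating the non-overlap bound is rejected by name", {
  expect_error(spectrum_segmentation(c(0, 1, 1.1, pi), c(0.2, 0.04)),
               "tau_1")
  expect_error(spectrum_segmentation(c(0, 1, 2, pi), c(0.1, -0.1)),
               "tau_2")
})

test_that("an in-band tone concentrates its energy in the matching detail", {
  rate <- 250; n <- 1024
  seg <- spectrum_segmentation(c(0, 0.8, 1.9, pi), c(0.08, 0.15))
  bank <- build_filter_bank(seg, n)
  # tone inside band 2 (omega in (0.88, 1.75)): omega = 2 pi f / rate
  f <- 1.3 * rate / (2 * pi)
  dec <- ewt_decompose(make_tone(f, rate, n), bank)
  comps <- c(list(dec$approx), dec$details)
  energies <- vapply(comps, function(z) sum(z^2), numeric(1))
  expect_gte(energies[2L] / sum(energies), 0.99)
})

test_that("the transform is linear and rejects mismatched lengths", {
  seg <- spectrum_segmentation(c(0, 1.2, pi), 0.12)
  bank <- build_filter_bank(seg, 256)
  z <- signal(rep(0, 256), 100)
  dz <- ewt_decompose(z, bank)
  expect_true(all(abs(c(dz$approx, unlist(dz$details))) == 0))

  set.seed(5)
  x <- rnorm(256)
  d1 <- ewt_decompose(signal(x, 100), bank)
  d3 <- ewt_decompose(signal(3 * x, 100), bank)
  expect_equal(d3$approx, 3 * d1$approx)
  expect_equal(d3$details[[1L]], 3 * d1$details[[1L]])

  expect_error(ewt_decompose(signal(rnorm(128), 100), bank), "match")
})

test_that("round-trip reconstruction is exact to 1e-8 over random signals", {
  set.seed(202)
  worst <- 0
  for (i in 1:100) {
    n <- sample(c(64, 128, 256, 512, 1024, 4096), 1)
    x <- rnorm(n)
    supports <- sample(1:6, 1)
    seg <- quiet(detect_boundaries(pos_magnitude(x), supports))
    dec <- ewt_decompose(signal(x, 250), build_filter_bank(seg, n))
    worst <- max(worst, rel_l2(ewt_reconstruct(dec)$samples, x))
  }
  expect_lt(worst, 1e-8)
})

test_that("reconstruction is linear and N = 1 keeps the signal in the approximation", {
  x <- rnorm(128)
  sig <- signal(x, 100)
  bank <- build_filter_bank(spectrum_segmentation(c(0, pi)), 128)
  dec <- ewt_decompose(sig, bank)
  expect_equal(dec$approx, x)                        # phi == 1 when N = 1
  expect_length(dec$details, 0L)

  seg <- spectrum_segmentation(c(0, 1.2, pi), 0.12)
  dec2 <- ewt_decompose(sig, build_filter_bank(seg, 128))
  dec2s <- dec2
  dec2s$approx <- 2 * dec2$approx
  dec2s$details <- lapply(dec2$details, function(d) 2 * d)
  expect_equal(ewt_reconstruct(dec2s)$samples, 2 * ewt_reconstruct(dec2)$samples)

  dec2z <- dec2
  dec2z$approx <- 0 * dec2$approx
  dec2z$details <- lapply(dec2$details, function(d) 0 * d)
  expect_true(all(ewt_reconstruct(dec2z)$samples == 0))

  dec2nb <- dec2
  dec2nb$bank <- NULL
  expect_error(ewt_reconstruct(dec2nb), "bank")
})
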