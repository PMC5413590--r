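# Shared fixtures and independent oracles.

quiet <- function(expr) suppressMessages(expr)

# fast encoding config for tests
test_config <- function(...) {
  fewt_config(fcm = list(restarts = 2L), ...)
}

pos_magnitude <- function(x) {
  n <- length(x)
  Mod(stats::fft(x))[1:(n %/% 2L + 1L)]
}

make_tone <- function(freq, rate = 250, n = 1024) {
  signal(cos(2 * pi * freq * (0:(n - 1)) / rate), rate)
}

partition_of_unity <- function(bank) {
  filters <- c(list(bank$scaling), bank$wavelets)
  Reduce(`+`, lapply(filters, function(f) f^2))
}

rel_l2 <- function(a, b) {
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

# Independent LZ76 parser: exhaustive-history parsing by direct substring
# search, O(n^3); used only as an oracle on short strings.
lz76_oracle_count <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  cn <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    # grow the phrase while s[i..i+l-1] occurs in s[1..i+l-2]
    while (i + l - 1L <= n) {
      phrase <- substr(s, i, i + l - 1L)
      hist <- substr(s, 1L, i + l - 2L)
      if (i + l - 1L > n || !grepl(phrase, hist, fixed = TRUE)) break
      l <- l + 1L
    }
    cn <- cn + 1L
    i <- i + l
  }
  cn
}

# Independent FCM objective oracle for 1-D, c = 2, m = 2: for fixed
# centroids the optimal memberships give objective sum_j 1/sum_i (1/d2_ij);
# minimized by staged dense grid search over centroid pairs.
fcm_grid_oracle <- function(x, levels = 3L, grid_n = 61L) {
  obj_of <- function(v1, v2) {
    d1 <- (x - v1)^2
    d2 <- (x - v2)^2
    d1 <- pmax(d1, 1e-300)
    d2 <- pmax(d2, 1e-300)
    sum(1 / (1 / d1 + 1 / d2))
  }
  lo1 <- lo2 <- min(x); hi1 <- hi2 <- max(x)
  best <- Inf
  for (lv in seq_len(levels)) {
    g1 <- seq(lo1, hi1, length.out = grid_n)
    g2 <- seq(lo2, hi2, length.out = grid_n)
    vals <- outer(g1, g2, Vectorize(obj_of))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1L, ]
    best <- min(vals)
    st1 <- g1[2L] - g1[1L]; st2 <- g2[2L] - g2[1L]
    lo1 <- g1[ix[1L]] - st1; hi1 <- g1[ix[1L]] + st1
    lo2 <- g2[ix[2L]] - st2; hi2 <- g2[ix[2L]] + st2
  }
  best
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

withr_local_tempdir <- function() {
  d <- tempfile("fewt")
  dir.create(d)
  d
}

# toy accuracy table used by ranking tests
toy_acc_table <- function() {
  expand.grid(
    task_pair = c("BvL", "BvM"),
    extraction = c("EWT", "FEWT"),
    selection = c("WFS", "LR"),
    stringsAsFactors = FALSE
  )
}
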