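test_that("class statistics match hand computation", {
  x <- rbind(c(0, 0), c(2, 2), c(10, 10), c(12, 12))
  st <- class_statistics(x, c("A", "A", "B", "B"))
  expect_equal(unname(st$means["A", ]), c(1, 1))
  expect_equal(unname(st$means["B", ]), c(11, 11))
  expect_equal(unname(st$priors), c(0.5, 0.5))
  expect_equal(unname(st$global_mean), c(6, 6))

  one <- class_statistics(matrix(rnorm(10), 5), rep("A", 5))
  expect_equal(unname(one$priors), 1)
  expect_equal(unname(one$global_mean), unname(one$means["A", ]))

  dup <- class_statistics(rbind(x, x), rep(c("A", "A", "B", "B"), 2))
  expect_equal(dup$means, st$means)
  expect_equal(dup$priors, st$priors)
})

test_that("Bhattacharyya/Chernoff distances match their closed forms", {
  set.seed(81)
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40), 20))
  lab <- rep(c("A", "B"), each = 20)
  same <- class_statistics(rbind(x[1:20, ], x[1:20, ]), lab)
  expect_equal(chernoff_distance(same, beta = 0.3), 0)
  expect_equal(bhattacharyya_distance(same), 0)

  # equal covariance reduction: J_B = (1/8) dmu' S^-1 dmu; dmu=(2,0), S=I -> 0.5
  st <- class_statistics(x, lab)
  st$means <- rbind(A = c(0, 0), B = c(2, 0))
  st$covariances <- list(A = diag(2), B = diag(2))
  expect_equal(bhattacharyya_distance(st), 0.5, tolerance = 1e-10)

  # 1-D variance-only case: S1=1, S2=4 -> 0.5*log(2.5/2)
  st1 <- class_statistics(matrix(rnorm(40), 40), rep(c("A", "B"), each = 20))
  st1$means <- rbind(A = 0, B = 0)
  st1$covariances <- list(A = matrix(1), B = matrix(4))
  expect_equal(bhattacharyya_distance(st1), 0.5 * log(2.5 / 2), tolerance = 1e-12)
  expect_equal(0.5 * log(2.5 / 2), 0.11157, tolerance = 1e-4)
})

test_that("Chernoff at beta = 1/2 equals BD and the measure is symmetric", {
  set.seed(91)
  for (i in 1:10) {
    x <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 1), 20, 3))
    lab <- rep(c("A", "B"), each = 20)
    st <- class_statistics(x, lab)
    expect_identical(chernoff_distance(st, beta = 0.5), bhattacharyya_distance(st))
    expect_gte(bhattacharyya_distance(st), 0)
    swapped <- class_statistics(x, rep(c("B", "A"), each = 20))
    expect_equal(bhattacharyya_distance(swapped), bhattacharyya_distance(st),
                 tolerance = 1e-12)
  }
  st <- class_statistics(matrix(rnorm(40), 20, 2), rep(c("A", "B"), 10))
  expect_error(chernoff_distance(st, beta = 1.2), "0, 1")
  expect_error(
    chernoff_distance(class_statistics(matrix(rnorm(30), 15), rep(c("A", "B", "C"), 5))),
    "two-class"
  )
})

test_that("scatter ratio matches the 1-D hand example and its invariances", {
  x <- c(-1, 1, 9, 11)
  lab <- c("A", "A", "B", "B")
  expect_equal(scatter_ratio(x, lab), 25)

  # identical class means -> zero between-class scatter
  expect_equal(scatter_ratio(c(-1, 1, -1, 1), lab), 0)

  set.seed(101)
  xm <- matrix(rnorm(80), 20, 4)
  labm <- rep(c("A", "B"), 10)
  q <- qr.Q(qr(matrix(rnorm(16), 4)))        # random orthogonal map
  expect_equal(scatter_ratio(xm %*% q, labm), scatter_ratio(xm, labm),
               tolerance = 1e-9)

  expect_error(scatter_ratio(c(1, 1, 2, 2), lab), "within-class")
})

test_that("LR criterion is the coefficient of determination, bounded in [0,1]", {
  set.seed(111)
  x <- matrix(rnorm(200), 100, 2)
  y <- 2 * x[, 1] - x[, 2] + 3
  expect_equal(lr_criterion(x, y), 1)

  expect_equal(lr_criterion(rep(1, 50), rep(c(0, 1), 25)), 0)

  f1 <- rnorm(500)
  eps <- rnorm(500, sd = 1.5)
  r2 <- lr_criterion(matrix(f1), f1 + eps)
  pop <- stats::var(f1) / (stats::var(f1) + 1.5^2)
  expect_lt(abs(r2 - pop), 0.05)

  for (i in 1:50) {
    n <- sample(20:60, 1)
    xx <- matrix(rnorm(n * 3), n, 3)
    yy <- sample(0:1, n, replace = TRUE)
    if (stats::var(yy) == 0) next
    v <- lr_criterion(xx, yy)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(lr_criterion(matrix(rnorm(10)), rep(1, 10)), "constant target")
})

test_that("the informative column is ranked first by all three criteria", {
  set.seed(121)
  n <- 60
  lab <- rep(c("A", "B"), each = n / 2)
  x <- cbind(ifelse(lab == "A", 0, 6) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 7), n, 7))
  for (cr in c("bd", "sr", "lr")) {
    sel <- forward_select(x, lab, cr, k = 3)
    expect_equal(sel$ranked_indices[1L], 1L)
    expect_length(sel$criterion_trace, 3L)
  }
})

test_that("greedy selection equals exhaustive subset recomputation (k <= 3, <= 6 cols)", {
  set.seed(131)
  n <- 40
  lab <- rep(c("A", "B"), each = n / 2)
  x <- cbind(ifelse(lab == "A", 0, 2) + rnorm(n), matrix(rnorm(n * 5), n, 5))
  for (cr in c("bd", "sr", "lr")) {
    crit <- fewt:::criterion_fun(cr)
    sel <- forward_select(x, lab, cr, k = 3)
    chosen <- integer(0)
    for (step in 1:3) {
      cand <- setdiff(1:6, chosen)
      vals <- vapply(cand, function(j) {
        quiet(crit(x[, c(chosen, j), drop = FALSE], lab))
      }, numeric(1))
      best <- cand[which.max(vals)]
      expect_identical(sel$ranked_indices[step], best)
      expect_equal(sel$criterion_trace[step], max(vals))
      chosen <- c(chosen, best)
    }
  }
})

test_that("k = 1 is the singleton argmax and full k is a permutation", {
  set.seed(141)
  n <- 30
  lab <- rep(c("A", "B"), each = 15)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 3] <- x[, 3] + ifelse(lab == "A", 0, 1.5)
  singles <- vapply(1:5, function(j) scatter_ratio(x[, j], lab), numeric(1))
  expect_equal(forward_select(x, lab, "sr", k = 1)$ranked_indices,
               which.max(singles))
  expect_setequal(forward_select(x, lab, "lr", k = 5)$ranked_indices, 1:5)
})

test_that("an exact duplicate of a chosen column adds (almost) nothing under SR", {
  set.seed(151)
  n <- 80
  lab <- rep(c("A", "B"), each = n / 2)
  informative <- ifelse(lab == "A", 0, 4) + rnorm(n, sd = 0.5)
  x <- cbind(informative, informative, matrix(rnorm(n * 3), n, 3))
  sel <- forward_select(x, lab, "sr", k = 4)
  expect_equal(sel$ranked_indices[1L], 1L)
  dup_step <- match(2L, sel$ranked_indices)
  if (!is.na(dup_step) && dup_step > 1L) {
    gain <- sel$criterion_trace[dup_step] - sel$criterion_trace[dup_step - 1L]
    expect_lt(gain, 1e-9)
  }
})
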