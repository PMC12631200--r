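test_that("ISIC matches hand-worked and degenerate cases", {
  # zero within-class spread, separated means
  x0 <- matrix(c(0.2, 0.2, 0.4, 0.4), ncol = 1)
  expect_equal(isic_values(x0, c("a", "a", "b", "b")), 0)
  # identical class means
  xi <- matrix(c(0.1, 0.3, 0.3, 0.1), ncol = 1)
  expect_equal(isic_values(xi, c("a", "a", "b", "b")), Inf)
  # three classes, hand-computed pair terms
  x3 <- matrix(c(1, 3, 5, 7, 9, 11), ncol = 1)
  expect_equal(isic_values(x3, rep(c("a", "b", "c"), each = 2)),
               (2 * sqrt(2) / 4 + 2 * sqrt(2) / 8 + 2 * sqrt(2) / 4) / 3,
               tolerance = 1e-12)
  expect_error(isic_values(x3, rep("a", 6)), "2 classes")
  expect_error(isic_values(x3, c("a", "b", "b", "b", "b", "b")), "2 samples")
})

test_that("vectorized ISIC equals the brute-force oracle on random data", {
  set.seed(100)
  for (rep in 1:100) {
    n_class <- sample(2:4, 1)
    n_per <- sample(3:6, 1)
    b <- sample(2:8, 1)
    x <- matrix(rnorm(n_class * n_per * b), n_class * n_per, b)
    labels <- rep(letters[1:n_class], each = n_per)
    expect_equal(isic_values(x, labels), brute_isic(x, labels), tolerance = 1e-10)
  }
})

test_that("ISIC is invariant to positive rescaling and monotone in separation", {
  set.seed(7)
  x <- matrix(rnorm(60), 12, 5)
  labels <- rep(c("a", "b", "c"), each = 4)
  base <- isic_values(x, labels)
  for (c0 in c(0.001, 0.5, 7, 1e4)) {
    expect_equal(isic_values(c0 * x, labels), base, tolerance = 1e-9)
  }
  # widen every pairwise mean separation at one band, sds fixed: ISIC drops
  x2 <- x
  x2[labels == "b", 3] <- x2[labels == "b", 3] + 5
  x2[labels == "c", 3] <- x2[labels == "c", 3] + 10
  expect_lt(isic_values(x2, labels)[3], base[3])
})

test_that("adjacent-difference series follows the definition and propagates Inf", {
  expect_equal(di_series(c(0.5, 0.5, 0.5)), c(0, 0))
  expect_equal(di_series(c(0.1, 0.4, 0.2)), c(0.3, 0.2))
  d <- di_series(c(0.1, Inf, 0.2, 0.3))
  expect_equal(d, c(Inf, Inf, 0.1))
  expect_equal(di_series(c(Inf, Inf)), Inf)
  expect_error(di_series(0.3), ">= 2")
})

test_that("threshold filtering applies the removal rule and is monotone in T", {
  # D = (0.3, 0.2), T = 0.25: band 1 removed, bands 2 and 3 kept
  expect_equal(filter_by_threshold(c(0.3, 0.2), 0.25), c(2L, 3L))
  d <- abs(diff(c(0.3, 0.1, 0.7, 0.2, 0.25)))
  expect_equal(filter_by_threshold(d, Inf), 1:5)
  expect_error(filter_by_threshold(c(1, 2, 3), 0), "degenerate")
  # monotone: retained(T1) subset of retained(T2) for T1 <= T2
  set.seed(3)
  dr <- runif(20)
  ts <- sort(runif(6, 0, 1))
  sets <- lapply(ts, function(t0)
    tryCatch(filter_by_threshold(dr, t0), error = function(e) integer(0)))
  for (i in 1:5) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("spa_chain equals the Gram-Schmidt oracle on random matrices, all starts", {
  set.seed(200)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    b <- sample(2:6, 1)
    x <- matrix(rnorm(n * b), n, b)
    k <- min(b, n - 1)
    for (s in seq_len(b)) {
      expect_equal(spa_chain(x, s, k), brute_spa(x, s, k),
                   info = sprintf("rep %d start %d", rep, s))
    }
  }
})

test_that("spa_chain handles orthogonal, duplicated and rank-deficient inputs", {
  # centered orthogonal columns with norms 3, 2, 1: greedy order by norm
  h <- stats::contr.helmert(6)[, 1:3]
  x <- h %*% diag(c(3, 2, 1) / sqrt(colSums(h^2)))
  expect_equal(spa_chain(x, start = 2, k_max = 3), c(2L, 1L, 3L))
  expect_equal(spa_chain(x, start = 2, k_max = 1), 2L)
  # an exact duplicate column is never selected after its twin
  set.seed(5)
  xd <- matrix(rnorm(30), 10, 3)
  xd <- cbind(xd, xd[, 2])
  for (s in 1:4) {
    ch <- spa_chain(xd, s, 4)
    expect_false(all(c(2, 4) %in% ch))
    expect_equal(anyDuplicated(ch), 0L)
  }
  # k_max beyond rank: chain truncates without error
  xr <- cbind(1:6, (1:6) * 2, rnorm(6))
  expect_lte(length(spa_chain(xr, 1, 3)), 2)
})

test_that("residual norms are non-increasing after the forced start", {
  set.seed(11)
  x <- scale(matrix(rnorm(80), 10, 8), center = TRUE, scale = FALSE)
  chain_norms <- function(start) {
    ch <- spa_chain(x, start, 6)
    vapply(seq_along(ch), function(i) {
      if (i == 1) return(sqrt(sum(x[, ch[1]]^2)))
      q <- qr.Q(qr(x[, ch[1:(i - 1)], drop = FALSE]))
      r <- x[, ch[i]] - q %*% crossprod(q, x[, ch[i]])
      sqrt(sum(r^2))
    }, numeric(1))
  }
  # the start band is forced, so monotonicity is guaranteed from step 2 on;
  # starting at the largest-norm column it holds along the whole chain
  for (s in 1:8) {
    norms <- chain_norms(s)
    expect_true(all(diff(norms[-1]) <= 1e-9), info = paste("start", s))
  }
  best <- which.max(sqrt(colSums(x^2)))
  expect_true(all(diff(chain_norms(best)) <= 1e-9))
})

test_that("threshold search recovers a planted informative band", {
  hits <- 0L
  for (s in 1:5) {
    pl <- make_planted_spectra(n_per_class = c(12, 12, 12), planted = 700,
                               delta = 0.03, seed = s)
    # sub-grid (with the planted band on it) keeps the search cheap
    sub <- sort(unique(c(seq(1, 145, by = 5), pl$planted_idx)))
    x <- pl$x[, sub]
    opt <- optimize_threshold(x, pl$stage, cv_cfg = fast_cv(folds = 4),
                              grid_cfg = grid_config(n_coarse = 6, n_refine = 2))
    target <- which(sub == pl$planted_idx[1])
    if (length(target) && target %in% opt$retained) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("threshold search honours degenerate grids and the fewest-bands tie-break", {
  pl <- make_planted_spectra(n_per_class = c(8, 8, 8), planted = 700,
                             delta = 0.05, seed = 3)
  x <- pl$x[, seq(1, 145, by = 12)]
  opt1 <- optimize_threshold(x, pl$stage, cv_cfg = fast_cv(folds = 4),
                             grid_cfg = grid_config(n_coarse = 1, n_refine = 0))
  expect_equal(nrow(opt1$curve), 1L)
  expect_equal(opt1$threshold, opt1$curve$threshold[1])
  # huge tolerance: every threshold ties, fewest-bands candidate wins
  opt2 <- optimize_threshold(x, pl$stage, cv_cfg = fast_cv(folds = 4),
                             grid_cfg = grid_config(n_coarse = 6, n_refine = 1,
                                                    tolerance = 1))
  ok <- opt2$curve[!is.na(opt2$curve$cv_acc), ]
  expect_equal(length(opt2$retained), min(ok$n_bands))
})

test_that("spa_select sizes the subset by the accuracy curve and tolerance", {
  pl <- make_planted_spectra(n_per_class = c(15, 15, 15), delta = 0.03, seed = 2)
  x <- pl$x[, seq(1, 145, by = 6)]
  wl <- pl$wavelengths[seq(1, 145, by = 6)]
  res <- spa_select(x, pl$stage, cv_cfg = fast_cv(), k_max = 4,
                    starts = c(1, 10, 20), wavelengths = wl)
  expect_true(all(res$curve$cv_acc >= 0 & res$curve$cv_acc <= 1))
  expect_equal(anyDuplicated(res$selected), 0L)
  expect_equal(length(res$selected), res$k)
  # tolerance 1 forces the one-band subset
  res1 <- spa_select(x, pl$stage, cv_cfg = fast_cv(), k_max = 4,
                     starts = c(1, 10, 20), tolerance = 1)
  expect_equal(res1$k, 1L)
})

test_that("isic_spa_select restricted to two bands chooses within them", {
  set.seed(21)
  n <- 30
  stage <- rep(damage_stages(), each = 10)
  shift <- (match(stage, damage_stages()) - 1) * 0.05
  # band 1 informative and stable; band 2 informative; bands 3-4 noisy steps
  x <- cbind(0.3 + shift + rnorm(n, 0, 0.01),
             0.5 + shift + rnorm(n, 0, 0.01),
             rnorm(n, 0.4, 0.01),
             rnorm(n, 0.4, 0.01))
  res <- spa_select(x[, 1:2], stage, cv_cfg = fast_cv(folds = 3), k_max = 2)
  expect_true(all(res$selected %in% 1:2))
})
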