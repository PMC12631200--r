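make_tiny_spectra <- function(refl, wavelengths, stage = NULL) {
  n <- nrow(refl)
  colnames(refl) <- sprintf("%.2f", wavelengths)
  if (is.null(stage)) stage <- rep(damage_stages(), length.out = n)
  out <- data.frame(tree_id = sprintf("t%02d", seq_len(n)),
                    stage = factor(stage, levels = damage_stages(), ordered = TRUE),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(refl, check.names = FALSE))
  attr(out, "wavelengths") <- wavelengths
  class(out) <- c("spectra_table", "data.frame")
  out
}

test_that("vegetation indices follow their closed forms", {
  wl <- c(686, 759, 926)
  refl <- rbind(c(0.05, 0.45, 0.35),
                c(0.30, 0.30, 0.30))
  st <- make_tiny_spectra(refl, wl)
  expect_equal(compute_vi(st, vi_definition("NDSI", 759, 686)), c(0.8, 0))
  expect_equal(compute_vi(st, vi_definition("DSI", 759, 686)), c(0.40, 0))
  expect_equal(compute_vi(st, vi_definition("RSI", 759, 686)), c(9.0, 1))
  expect_equal(compute_vi(st, vi_definition("RA", 686, 759, 926)),
               c(0.05 / 0.80, 0.5))
  # zero denominator names the tree and family
  refl0 <- rbind(c(0.1, 0, 0.2))
  st0 <- make_tiny_spectra(refl0, wl)
  expect_error(compute_vi(st0, vi_definition("RSI", 686, 759)), "t01.*RSI")
})

test_that("index families obey their antisymmetry identities", {
  set.seed(4)
  wl <- seq(500, 900, length.out = 6)
  refl <- matrix(runif(60, 0.05, 0.6), 10, 6)
  st <- make_tiny_spectra(refl, wl)
  for (pair in list(c(500, 660), c(580, 900))) {
    a <- pair[1]; b <- pair[2]
    expect_equal(compute_vi(st, vi_definition("NDSI", a, b)),
                 -compute_vi(st, vi_definition("NDSI", b, a)))
    expect_equal(compute_vi(st, vi_definition("DSI", a, b)),
                 -compute_vi(st, vi_definition("DSI", b, a)))
    expect_equal(compute_vi(st, vi_definition("RSI", a, b)),
                 1 / compute_vi(st, vi_definition("RSI", b, a)))
  }
})

test_that("spearman_rho reproduces rank-Pearson values", {
  expect_equal(spearman_rho(1:6, 2 * (1:6)), 1)
  expect_equal(spearman_rho(6:1, 1:6), -1)
  # mid-ranks with ties in y, hand value 0.8944
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 1, 2, 2)), 0.894427191,
               tolerance = 1e-8)
  expect_error(spearman_rho(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("vi_search enumerates ordered combinations and finds planted signal", {
  # candidate counts over three bands: 6 ordered pairs, 6 ordered triples
  wl <- c(686, 759, 926)
  n <- 0
  for (a in wl) for (b in wl) if (a != b) n <- n + 1
  expect_equal(n, 6)
  n3 <- 0
  for (a in wl) for (b in wl) for (c0 in wl)
    if (length(unique(c(a, b, c0))) == 3) n3 <- n3 + 1
  expect_equal(n3, 6)

  # only 686 and 759 carry stage signal: DSI winner uses exactly those
  wins <- 0L
  for (s in 1:5) {
    # opposite-signed responses at 686 and 759, as on a shifting red edge
    pl <- make_planted_spectra(planted = c(686, 759), delta = c(-0.03, 0.03),
                               seed = s)
    res <- vi_search(pl$spectra, c(686, 759, 926))
    got <- sort(round(res$DSI$wavelengths))
    grid_expect <- sort(round(pl$wavelengths[vapply(c(686, 759), function(w)
      which.min(abs(pl$wavelengths - w)), integer(1))]))
    if (identical(got, grid_expect)) wins <- wins + 1L
  }
  expect_equal(wins, 5L)
})

test_that("the winning index has the largest |rho| in its family", {
  pl <- make_planted_spectra(seed = 9)
  res <- vi_search(pl$spectra, c(686, 759, 926))
  codes <- as.integer(pl$stage)
  wl_sel <- pl$wavelengths[pl$planted_idx]
  best <- abs(attr(res$NDSI, "rho"))
  for (a in wl_sel) for (b in wl_sel) {
    if (a == b) next
    v <- compute_vi(pl$spectra, vi_definition("NDSI", a, b))
    expect_lte(abs(spearman_rho(v, codes)), best + 1e-9)
  }
})

test_that("height and AIH metrics match their stated definitions", {
  cl <- data.frame(x = 0, y = 0, z = c(1, 2, 3, 4, 1.5, 2.5, 3.5, 1.2, 2.2, 3.2),
                   intensity = rep(c(100, 120), 5))
  m <- lidar_metrics(cl)
  expect_equal(m$elev_percentile_10th, unname(quantile(cl$z, 0.10)))
  expect_equal(m$elev_percentile_30th, unname(quantile(cl$z, 0.30)))
  # worked AIH example on z = 1..4
  expect_equal(aih_percentile(c(1, 2, 3, 4), 50), 3)
  expect_equal(aih_percentile(c(1, 2, 3, 4), 100), 4)
  z <- runif(50, 1, 8)
  expect_equal(aih_percentile(z, 100), max(z))
  # symmetric two-point intensities: skewness 0, excess kurtosis -2
  expect_equal(m$int_skewness, 0, tolerance = 1e-12)
  expect_equal(m$int_kurtosis, -2, tolerance = 1e-12)
  expect_equal(m$int_p50, 110)
  # percentile and AIH are non-decreasing in p
  ps <- c(5, 10, 25, 50, 75, 95, 100)
  qv <- vapply(ps, function(p) unname(quantile(z, p / 100)), numeric(1))
  av <- vapply(ps, function(p) aih_percentile(z, p), numeric(1))
  expect_true(all(diff(qv) >= 0))
  expect_true(all(diff(av) >= 0))
  # the 0.5 m height filter and the minimum-point rule
  low <- data.frame(x = 0, y = 0, z = runif(30, 0, 0.4), intensity = 1)
  expect_error(lidar_metrics(low), "insufficient")
})

test_that("AIH responds to lower-crown point loss only when removal is biased", {
  aih_by_dp <- function(bias, dp, n = 100) {
    vapply(seq_len(n), function(s) {
      cl <- generate_tree_cloud(dp, crown_config(removal_bias = bias, seed = 1000 + s))
      lidar_metrics(cl)$elev_AIH_5th
    }, numeric(1))
  }
  biased_lo <- mean(aih_by_dp(2, 5))
  biased_hi <- mean(aih_by_dp(2, 70))
  expect_gt(biased_hi, biased_lo)
  unb_lo <- mean(aih_by_dp(0, 5))
  unb_hi <- mean(aih_by_dp(0, 70))
  # uniform thinning leaves the cumulative-height quantile nearly unbiased
  expect_lt(abs(unb_hi - unb_lo), (biased_hi - biased_lo) / 3)
})

test_that("intensity moments converge on large Gaussian samples", {
  set.seed(77)
  n <- 5e4
  cl <- data.frame(x = 0, y = 0, z = runif(n, 1, 6),
                   intensity = rnorm(n, 130, 15))
  m <- lidar_metrics(cl)
  expect_equal(m$int_mean, 130, tolerance = 4 * 15 / sqrt(n))
  expect_equal(m$int_kurtosis, 0, tolerance = 4 * sqrt(24 / n))
  expect_equal(m$int_skewness, 0, tolerance = 4 * sqrt(6 / n))
})

test_that("feature table joins VIs and LiDAR metrics one row per tree", {
  st <- generate_spectra_dataset(spectra_config(n_per_class = c(5, 5, 5), seed = 6L))
  clouds <- lapply(seq_len(nrow(st)), function(i)
    generate_tree_cloud(st$dp[i], crown_config(seed = 600 + i), st$tree_id[i]))
  names(clouds) <- st$tree_id
  defs <- list(vi_definition("DSI", 759, 686), vi_definition("NDSI", 759, 686))
  ft <- build_feature_table(st, clouds, defs)
  expect_equal(nrow(ft), 15)
  expect_true(all(c("DSI_759_686", "NDSI_759_686", "elev_AIH_5th", "int_kurtosis")
                  %in% names(ft)))
  expect_false(anyNA(ft))
})
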