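# Independent brute-force oracles and small fixture builders.

# ISIC by direct scalar loops over bands and unordered class pairs.
brute_isic <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  lev <- levels(labels)
  m <- length(lev)
  vapply(seq_len(ncol(x)), function(i) {
    terms <- c()
    for (z in 1:(m - 1)) {
      for (j in (z + 1):m) {
        vz <- x[labels == lev[z], i]
        vj <- x[labels == lev[j], i]
        den <- abs(mean(vz) - mean(vj))
        terms <- c(terms, if (den < 1e-12) Inf else (sd(vz) + sd(vj)) / den)
      }
    }
    mean(terms)
  }, numeric(1))
}

# SPA by explicit Gram-Schmidt: at each step orthonormalize the chosen
# columns with QR and pick the unchosen column with the largest residual.
brute_spa <- function(x, start, k_max, tol = 1e-9) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  cutoff <- tol * max(sqrt(colSums(x^2)), .Machine$double.eps)
  chain <- integer(0)
  current <- start
  for (step in seq_len(min(k_max, ncol(x)))) {
    if (length(chain) == 0L) {
      resid_cur <- x[, current]
    } else {
      q <- qr.Q(qr(x[, chain, drop = FALSE]))
      resid_cur <- x[, current] - q %*% crossprod(q, x[, current])
    }
    if (sqrt(sum(resid_cur^2)) <= cutoff) break
    chain <- c(chain, current)
    if (length(chain) == min(k_max, ncol(x))) break
    q <- qr.Q(qr(x[, chain, drop = FALSE]))
    norms <- vapply(seq_len(ncol(x)), function(c0) {
      if (c0 %in% chain) return(-Inf)
      r <- x[, c0] - q %*% crossprod(q, x[, c0])
      sqrt(sum(r^2))
    }, numeric(1))
    current <- which.max(norms)
    if (norms[current] <= cutoff) break
  }
  chain
}

# Kruskal-Wallis H from the rank formula with tie correction.
brute_kw_h <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, idx, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Spectra with class signal only at the bands nearest the given wavelengths:
# flat baseline plus white noise, with class offsets at the planted bands.
# Signal is deliberately absent everywhere else. `delta` gives a linear
# per-class step per band; `offsets` (bands x 3 classes) overrides it with
# arbitrary per-band response patterns, so planted bands can carry
# complementary rather than collinear information.
make_planted_spectra <- function(n_per_class = c(25, 25, 25),
                                 planted = c(686, 759, 926),
                                 delta = 0.02, offsets = NULL,
                                 noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  wl <- seq(400, 1000, length.out = 145)
  idx <- vapply(planted, function(w) which.min(abs(wl - w)), integer(1))
  if (is.null(offsets)) {
    delta <- rep_len(delta, length(idx))
    offsets <- outer(delta, 0:2)
  }
  n <- sum(n_per_class)
  stage <- rep(damage_stages(), n_per_class)
  x <- matrix(rnorm(n * length(wl), 0.3, noise_sd), n, length(wl))
  code <- match(stage, damage_stages())
  for (k in seq_along(idx)) x[, idx[k]] <- x[, idx[k]] + offsets[k, code]
  colnames(x) <- sprintf("%.2f", wl)
  out <- data.frame(tree_id = sprintf("t%03d", seq_len(n)),
                    stage = factor(stage, levels = damage_stages(), ordered = TRUE),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(x, check.names = FALSE))
  attr(out, "wavelengths") <- wl
  class(out) <- c("spectra_table", "data.frame")
  list(spectra = out, x = x, stage = out$stage, wavelengths = wl, planted_idx = idx)
}

fast_cv <- function(folds = 5L, ntree = 100L, seed = 7L) {
  cv_config(folds = folds, ntree = ntree, seed = seed)
}
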