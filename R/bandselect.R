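#' Per-band instability index between classes (ISIC)
#'
#' For band i with class means m_{z,i} and class standard deviations
#' S_{z,i}, ISIC_i is the mean over all unordered class pairs (z, j) of
#' (S_{z,i} + S_{j,i}) / |m_{z,i} - m_{j,i}| -- the ratio of within-class
#' spread to between-class separation. Lower values mark bands more
#' suitable for classification. A pair whose class means coincide (to
#' machine tolerance) makes the band's ISIC `+Inf`.
#'
#' @param x Trees x bands reflectance matrix, or a `spectra_table`.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples);
#'   taken from the table's `stage` column if `x` is a `spectra_table`.
#' @return Numeric vector of length `ncol(x)` (may contain `Inf`).
#' @export
isic_values <- function(x, labels = NULL) {
  if (inherits(x, "spectra_table")) {
    sm <- spectra_matrix(x)
    if (is.null(labels)) labels <- sm$stage
    x <- sm$x
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  counts <- table(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(counts < 2L)) {
    stop("every class needs >= 2 samples (class '",
         names(counts)[which(counts < 2L)[1]], "' has ", min(counts), ")",
         call. = FALSE)
  }
  lev <- levels(labels)
  m <- length(lev)
  means <- matrix(0, m, ncol(x))
  sds <- matrix(0, m, ncol(x))
  for (k in seq_len(m)) {
    xk <- x[labels == lev[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    sds[k, ] <- apply(xk, 2, stats::sd)
  }
  acc <- numeric(ncol(x))
  for (z in 1:(m - 1)) {
    for (j in (z + 1):m) {
      num <- sds[z, ] + sds[j, ]
      den <- abs(means[z, ] - means[j, ])
      tol <- .Machine$double.eps^0.5 * pmax(1, abs(means[z, ]), abs(means[j, ]))
      term <- ifelse(den <= tol, Inf, num / den)
      acc <- acc + term
    }
  }
  acc / (m * (m - 1) / 2)
}

#' Adjacent-band ISIC differences
#'
#' D_i = |ISIC_i - ISIC_{i+1}|; high D values flag unstable bands. `Inf`
#' ISIC entries propagate `Inf` to both adjacent differences (including
#' between two `Inf` neighbours).
#'
#' @param isic ISIC vector of length >= 2.
#' @return Nonnegative vector of length `length(isic) - 1`.
#' @export
di_series <- function(isic) {
  if (length(isic) < 2L) stop("need >= 2 ISIC values", call. = FALSE)
  d <- abs(diff(isic))
  d[is.nan(d)] <- Inf        # Inf - Inf: both bands maximally unstable
  d[is.infinite(isic[-length(isic)]) | is.infinite(isic[-1])] <- Inf
  d
}

#' Retain bands whose adjacent ISIC difference is at or below a threshold
#'
#' Band i (i < B) is removed iff D_i > T; the last band is judged by its
#' left difference D_{B-1}. Retention is monotone in T.
#'
#' @param d D series of length B - 1 (from [di_series()]).
#' @param threshold Nonnegative threshold T.
#' @return Integer indices of retained bands (1..B).
#' @export
filter_by_threshold <- function(d, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a single value >= 0", call. = FALSE)
  }
  b <- length(d) + 1L
  removed <- c(d > threshold, d[b - 1L] > threshold)
  retained <- which(!removed)
  if (length(retained) == 0L) {
    stop("degenerate selection: threshold removes every band", call. = FALSE)
  }
  retained
}

#' Cross-validation settings for wrapper band selection
#'
#' @param folds Number of stratified CV folds.
#' @param ntree Random-forest tree count used inside selection (kept
#'   moderate since the wrapper refits many times).
#' @param seed Integer seed controlling fold assignment and forests.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, ntree = 150L, seed = 42L) {
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  structure(list(folds = as.integer(folds), ntree = as.integer(ntree),
                 seed = as.integer(seed)), class = "cv_config")
}

#' Threshold-search settings for ISIC filtering
#'
#' @param n_coarse Number of points on the initial coarse grid over
#'   \[0, max finite D\].
#' @param n_refine Number of refinement rounds, each shrinking the step
#'   size tenfold around the incumbent threshold.
#' @param tolerance Accuracy tolerance: among thresholds within
#'   `tolerance` of the best CV accuracy, the one retaining fewest bands
#'   wins.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(n_coarse = 9L, n_refine = 2L, tolerance = 0.005) {
  if (n_coarse < 1L) stop("`n_coarse` must be >= 1", call. = FALSE)
  if (n_refine < 0L) stop("`n_refine` must be >= 0", call. = FALSE)
  structure(list(n_coarse = as.integer(n_coarse), n_refine = as.integer(n_refine),
                 tolerance = tolerance), class = "grid_config")
}

#' Tune the ISIC D threshold by cross-validated accuracy
#'
#' Evaluates mean stratified k-fold CV accuracy of the random-forest
#' classifier on the bands retained at each candidate threshold, first on
#' a coarse grid over \[0, max finite D\], then over `n_refine` rounds of
#' tenfold step reduction around the incumbent. Among thresholds whose
#' accuracy is within `tolerance` of the best, the one retaining fewest
#' bands (then the smallest threshold) is returned.
#'
#' @param x Trees x bands matrix, or a `spectra_table`.
#' @param labels Class labels (from the table if omitted).
#' @param cv_cfg A [cv_config()].
#' @param grid_cfg A [grid_config()].
#' @return List with `threshold`, `retained` (band indices), `isic`, `d`,
#'   and `curve` (data.frame threshold / n_bands / cv_acc).
#' @export
optimize_threshold <- function(x, labels = NULL, cv_cfg = cv_config(),
                               grid_cfg = grid_config()) {
  if (inherits(x, "spectra_table")) {
    sm <- spectra_matrix(x)
    if (is.null(labels)) labels <- sm$stage
    x <- sm$x
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  isic <- isic_values(x, labels)
  d <- di_series(isic)
  d_finite <- d[is.finite(d)]
  if (length(d_finite) == 0L) stop("no finite D values to tune over", call. = FALSE)
  d_max <- max(d_finite)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(thr) {
    retained <- tryCatch(filter_by_threshold(d, thr), error = function(e) NULL)
    if (is.null(retained)) return(list(acc = NA_real_, n = 0L, retained = NULL))
    key <- paste(retained, collapse = ",")
    if (!is.null(cache[[key]])) {
      return(list(acc = cache[[key]], n = length(retained), retained = retained))
    }
    acc <- cross_val_accuracy(x[, retained, drop = FALSE], labels,
                              folds = cv_cfg$folds,
                              rf_config(ntree = cv_cfg$ntree, seed = cv_cfg$seed),
                              seed = cv_cfg$seed)
    cache[[key]] <- acc
    list(acc = acc, n = length(retained), retained = retained)
  }

  results <- data.frame(threshold = numeric(0), n_bands = integer(0),
                        cv_acc = numeric(0))
  eval_grid <- function(grid) {
    for (thr in grid) {
      if (any(abs(results$threshold - thr) < 1e-15)) next
      r <- evaluate(thr)
      results[nrow(results) + 1L, ] <<- list(thr, r$n, r$acc)
    }
  }
  incumbent <- function() {
    ok <- results[!is.na(results$cv_acc), , drop = FALSE]
    if (nrow(ok) == 0L) stop("threshold search failed at every grid point", call. = FALSE)
    best <- max(ok$cv_acc)
    cand <- ok[ok$cv_acc >= best - grid_cfg$tolerance, , drop = FALSE]
    cand <- cand[order(cand$n_bands, cand$threshold), , drop = FALSE]
    cand$threshold[1]
  }

  if (grid_cfg$n_coarse == 1L) {
    eval_grid(d_max)
  } else {
    eval_grid(seq(0, d_max, length.out = grid_cfg$n_coarse))
  }
  step <- if (grid_cfg$n_coarse > 1L) d_max / (grid_cfg$n_coarse - 1L) else d_max
  for (round in seq_len(grid_cfg$n_refine)) {
    t0 <- incumbent()
    new_step <- step / 10
    grid <- seq(max(0, t0 - step), t0 + step, by = new_step)
    eval_grid(grid)
    step <- new_step
  }
  t_star <- incumbent()
  list(threshold = t_star,
       retained = filter_by_threshold(d, t_star),
       isic = isic, d = d,
       curve = results[order(results$threshold), , drop = FALSE])
}

#' Successive projections chain from one start band
#'
#' Classic SPA forward chain: columns are mean-centered; starting from
#' `start`, each step picks the column whose residual, after orthogonal
#' projection onto the span of the already chosen columns, has the largest
#' Euclidean norm. The chain stops early (without error) when every
#' remaining residual norm falls below `tol` times the largest initial
#' column norm, so selected columns stay linearly independent.
#'
#' @param x Samples x bands matrix.
#' @param start Index of the first band.
#' @param k_max Maximum chain length (`<= min(ncol, nrow - 1)` recommended).
#' @param tol Relative residual-norm tolerance for early stopping.
#' @return Integer vector of selected band indices, in selection order.
#' @export
spa_chain <- function(x, start, k_max, tol = 1e-9) {
  x <- as.matrix(x)
  if (start < 1L || start > ncol(x)) stop("`start` out of range", call. = FALSE)
  if (k_max < 1L) stop("`k_max` must be >= 1", call. = FALSE)
  r <- scale(x, center = TRUE, scale = FALSE)       # work on centered columns
  norm0 <- max(sqrt(colSums(r^2)))
  cutoff <- tol * max(norm0, .Machine$double.eps)
  chain <- integer(0)
  current <- as.integer(start)
  for (step in seq_len(min(k_max, ncol(x)))) {
    nrm <- sqrt(sum(r[, current]^2))
    if (nrm <= cutoff) break
    chain <- c(chain, current)
    u <- r[, current] / nrm
    r <- r - outer(u, drop(crossprod(r, u)))        # deflate chosen direction
    r[, chain] <- 0
    if (length(chain) == min(k_max, ncol(x))) break
    norms <- sqrt(colSums(r^2))
    norms[chain] <- -Inf
    current <- which.max(norms)
    if (norms[current] <= cutoff) break
  }
  chain
}

#' Wrapper band selection with the successive projections algorithm
#'
#' Launches an SPA chain from each start band (all bands by default;
#' `starts` may subsample for large grids). For each subset size k up to
#' `k_max`, every distinct chain prefix of length k is scored by mean
#' stratified k-fold CV accuracy of the random-forest classifier; the best
#' prefix defines the accuracy curve at k. The chosen size is the smallest
#' k whose accuracy is within `tolerance` of the curve maximum.
#'
#' @param x Trees x bands matrix, or a `spectra_table`.
#' @param labels Class labels (from the table if omitted).
#' @param cv_cfg A [cv_config()].
#' @param k_max Largest subset size considered.
#' @param starts Integer vector of start bands (default: every band).
#' @param tolerance Accuracy tolerance for the size tie-break.
#' @param wavelengths Optional wavelength grid for reporting.
#' @return A `band_selection` object: list with `method`, `selected`
#'   (indices), `wavelengths`, `k`, `curve` (size / cv_acc), and the best
#'   prefix per size.
#' @export
spa_select <- function(x, labels = NULL, cv_cfg = cv_config(), k_max = 10L,
                       starts = NULL, tolerance = 0.005, wavelengths = NULL) {
  if (inherits(x, "spectra_table")) {
    sm <- spectra_matrix(x)
    if (is.null(labels)) labels <- sm$stage
    if (is.null(wavelengths)) wavelengths <- sm$wavelengths
    x <- sm$x
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  k_max <- min(k_max, ncol(x), nrow(x) - 1L)
  if (is.null(starts)) starts <- seq_len(ncol(x))
  chains <- lapply(starts, function(s) spa_chain(x, s, k_max))

  cache <- new.env(parent = emptyenv())
  score <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    acc <- cross_val_accuracy(x[, idx, drop = FALSE], labels,
                              folds = cv_cfg$folds,
                              rf_config(ntree = cv_cfg$ntree, seed = cv_cfg$seed),
                              seed = cv_cfg$seed)
    cache[[key]] <- acc
    acc
  }

  curve <- data.frame(size = integer(0), cv_acc = numeric(0))
  best_prefix <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    prefixes <- unique(lapply(chains[vapply(chains, length, 1L) >= k],
                              function(ch) ch[seq_len(k)]))
    if (length(prefixes) == 0L) break
    accs <- vapply(prefixes, score, numeric(1))
    best <- which.max(accs)
    best_prefix[[k]] <- prefixes[[best]]
    curve[nrow(curve) + 1L, ] <- list(k, accs[best])
  }
  if (nrow(curve) == 0L) stop("no SPA chain reached length 1", call. = FALSE)
  best_acc <- max(curve$cv_acc)
  k_star <- min(curve$size[curve$cv_acc >= best_acc - tolerance])
  selected <- best_prefix[[k_star]]
  structure(list(
    method = "spa",
    selected = selected,
    wavelengths = if (!is.null(wavelengths)) wavelengths[selected] else NULL,
    k = k_star,
    curve = curve,
    prefixes = best_prefix[seq_len(nrow(curve))]
  ), class = "band_selection")
}

#' Chained ISIC-SPA band selection
#'
#' First removes unstable bands with the tuned ISIC D threshold
#' ([optimize_threshold()]), then runs [spa_select()] restricted to the
#' retained subset. The result records both stages; indices refer to the
#' original band grid.
#'
#' @inheritParams spa_select
#' @param grid_cfg A [grid_config()] for the threshold search.
#' @return A `band_selection` object with method `"isic-spa"` and an
#'   `isic_stage` element (threshold, retained indices, ISIC and D series).
#' @export
isic_spa_select <- function(x, labels = NULL, cv_cfg = cv_config(), k_max = 10L,
                            grid_cfg = grid_config(), starts = NULL,
                            tolerance = 0.005, wavelengths = NULL) {
  if (inherits(x, "spectra_table")) {
    sm <- spectra_matrix(x)
    if (is.null(labels)) labels <- sm$stage
    if (is.null(wavelengths)) wavelengths <- sm$wavelengths
    x <- sm$x
  }
  x <- as.matrix(x)
  labels <- factor(labels)
  stage1 <- optimize_threshold(x, labels, cv_cfg = cv_cfg, grid_cfg = grid_cfg)
  retained <- stage1$retained
  if (length(retained) < 2L) {
    stop("degenerate selection: ISIC stage retained fewer than 2 bands", call. = FALSE)
  }
  sub_starts <- if (is.null(starts)) NULL else match(intersect(starts, retained), retained)
  if (!is.null(sub_starts) && length(sub_starts) == 0L) sub_starts <- NULL
  res <- spa_select(x[, retained, drop = FALSE], labels, cv_cfg = cv_cfg,
                    k_max = min(k_max, length(retained)), starts = sub_starts,
                    tolerance = tolerance)
  res$selected <- retained[res$selected]
  res$prefixes <- lapply(res$prefixes, function(p) retained[p])
  res$wavelengths <- if (!is.null(wavelengths)) wavelengths[res$selected] else NULL
  res$method <- "isic-spa"
  res$isic_stage <- list(threshold = stage1$threshold, retained = retained,
                         isic = stage1$isic, d = stage1$d, curve = stage1$curve)
  res
}

#' ISIC band selection (threshold filter alone)
#'
#' Tunes the D threshold and returns every band it retains, with the
#' accuracy-versus-threshold curve.
#'
#' @inheritParams isic_spa_select
#' @return A `band_selection` object with method `"isic"`.
#' @export
isic_select <- function(x, labels = NULL, cv_cfg = cv_config(),
                        grid_cfg = grid_config(), wavelengths = NULL) {
  if (inherits(x, "spectra_table")) {
    sm <- spectra_matrix(x)
    if (is.null(labels)) labels <- sm$stage
    if (is.null(wavelengths)) wavelengths <- sm$wavelengths
    x <- sm$x
  }
  stage1 <- optimize_threshold(x, labels, cv_cfg = cv_cfg, grid_cfg = grid_cfg)
  structure(list(
    method = "isic",
    selected = stage1$retained,
    wavelengths = if (!is.null(wavelengths)) wavelengths[stage1$retained] else NULL,
    k = length(stage1$retained),
    threshold = stage1$threshold,
    curve = stage1$curve,
    isic = stage1$isic, d = stage1$d
  ), class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat("Band selection (", x$method, "): ", length(x$selected), " band(s)\n", sep = "")
  if (!is.null(x$wavelengths)) {
    cat("  wavelengths (nm):", paste(sprintf("%.1f", x$wavelengths), collapse = ", "), "\n")
  }
  if (!is.null(x$curve) && nrow(x$curve)) {
    cat("  best CV accuracy on curve:", sprintf("%.4f", max(x$curve$cv_acc, na.rm = TRUE)), "\n")
  }
  invisible(x)
}
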