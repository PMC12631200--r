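#' Define a narrowband vegetation index
#'
#' Four families over reflectances R at named wavelengths:
#' NDSI = (R_x1 - R_x2) / (R_x1 + R_x2); DSI = R_x1 - R_x2;
#' RSI = R_x1 / R_x2; RA = R_x1 / (R_x2 + R_x3).
#'
#' @param family One of `"NDSI"`, `"DSI"`, `"RSI"`, `"RA"`.
#' @param x1,x2,x3 Wavelengths in nm (`x3` only for RA); must be distinct
#'   within a definition.
#' @return A list of class `vi_definition`.
#' @export
vi_definition <- function(family, x1, x2, x3 = NULL) {
  family <- match.arg(family, c("NDSI", "DSI", "RSI", "RA"))
  wls <- c(x1, x2, x3)
  if (family == "RA" && length(wls) != 3L) stop("RA needs three wavelengths", call. = FALSE)
  if (family != "RA" && length(wls) != 2L) stop(family, " needs two wavelengths", call. = FALSE)
  if (anyDuplicated(wls)) stop("wavelengths within a definition must be distinct", call. = FALSE)
  structure(list(family = family, wavelengths = wls), class = "vi_definition")
}

#' Label for a vegetation-index definition, e.g. "DSI_759_686"
#' @param def A `vi_definition`.
#' @return Character scalar.
#' @export
vi_name <- function(def) {
  paste(c(def$family, sprintf("%d", round(def$wavelengths))), collapse = "_")
}

# nearest grid band for each requested wavelength
nearest_band <- function(wavelengths, grid) {
  vapply(wavelengths, function(w) which.min(abs(grid - w)), integer(1))
}

#' Compute a vegetation index for every tree
#'
#' Requested wavelengths are resolved to the nearest band on the grid.
#' A zero denominator for any tree is an error naming the tree and family.
#'
#' @param spectra A `spectra_table` (or trees x bands matrix with
#'   `wavelengths` supplied).
#' @param def A [vi_definition()].
#' @param wavelengths Wavelength grid when `spectra` is a bare matrix.
#' @return Numeric vector, one value per tree.
#' @export
compute_vi <- function(spectra, def, wavelengths = NULL) {
  if (inherits(spectra, "spectra_table")) {
    sm <- spectra_matrix(spectra)
    x <- sm$x
    wavelengths <- sm$wavelengths
  } else {
    x <- as.matrix(spectra)
    if (is.null(wavelengths)) stop("`wavelengths` required for a bare matrix", call. = FALSE)
  }
  idx <- nearest_band(def$wavelengths, wavelengths)
  r <- lapply(idx, function(i) unname(x[, i]))
  denom <- switch(def$family,
                  NDSI = r[[1]] + r[[2]],
                  DSI = NULL,
                  RSI = r[[2]],
                  RA = r[[2]] + r[[3]])
  if (!is.null(denom) && any(denom == 0)) {
    bad <- which(denom == 0)[1]
    id <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop(sprintf("zero denominator for tree '%s' in %s", id, def$family), call. = FALSE)
  }
  switch(def$family,
         NDSI = (r[[1]] - r[[2]]) / denom,
         DSI = r[[1]] - r[[2]],
         RSI = r[[1]] / denom,
         RA = r[[1]] / denom)
}

#' Spearman rank correlation (mid-ranks)
#'
#' Pearson correlation of mid-ranks; ties receive average ranks. Used to
#' score vegetation indices against ordinal damage-stage codes 1 < 2 < 3.
#'
#' @param x Numeric values.
#' @param y Numeric or ordered values of the same length (>= 3).
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Exhaustive vegetation-index search over selected bands
#'
#' Enumerates all ordered distinct wavelength pairs (NDSI, DSI, RSI) and
#' ordered distinct triples (RA) over the selected bands, scores each
#' candidate by |Spearman rho| against the ordinal stage codes
#' (mild = 1 < moderate = 2 < severe = 3), and returns the winner per
#' family. Ties break by lexicographic wavelength order.
#'
#' @param spectra A `spectra_table`.
#' @param bands Wavelengths (nm) of the selected bands; resolved to the
#'   nearest grid band. Needs >= 2 (>= 3 for RA; RA is skipped with a
#'   warning otherwise).
#' @param stage Stage labels (taken from the table if omitted).
#' @return Named list of winning `vi_definition`s (element per family),
#'   each carrying `rho` (signed) and `abs_rho` attributes.
#' @export
vi_search <- function(spectra, bands, stage = NULL) {
  sm <- spectra_matrix(spectra)
  if (is.null(stage)) stage <- sm$stage
  codes <- as.integer(factor(stage, levels = damage_stages(), ordered = TRUE))
  if (length(bands) < 2L) stop("need >= 2 selected bands", call. = FALSE)
  idx <- sort(unique(nearest_band(bands, sm$wavelengths)))
  wls <- sm$wavelengths[idx]
  if (length(wls) < 2L) stop("selected bands collapse to < 2 grid bands", call. = FALSE)

  # infeasible candidates (zero denominator for some tree) simply cannot win
  score <- function(def) {
    tryCatch({
      v <- compute_vi(spectra, def)
      abs(spearman_rho(v, codes))
    }, error = function(e) -Inf)
  }
  pick <- function(family, tuples) {
    best_def <- NULL
    best_score <- -Inf
    for (tp in tuples) {
      def <- if (length(tp) == 3L) vi_definition(family, tp[1], tp[2], tp[3])
             else vi_definition(family, tp[1], tp[2])
      s <- score(def)
      if (s > best_score + 1e-12) {           # strict improvement; first (lexicographic) wins ties
        best_score <- s
        best_def <- def
      }
    }
    if (is.null(best_def) || !is.finite(best_score)) {
      stop("no feasible ", family, " candidate over the selected bands", call. = FALSE)
    }
    v <- compute_vi(spectra, best_def)
    attr(best_def, "rho") <- spearman_rho(v, codes)
    attr(best_def, "abs_rho") <- best_score
    best_def
  }

  pairs <- list()
  for (a in wls) for (b in wls) if (a != b) pairs[[length(pairs) + 1L]] <- c(a, b)
  out <- list(NDSI = pick("NDSI", pairs),
              DSI = pick("DSI", pairs),
              RSI = pick("RSI", pairs))
  if (length(wls) >= 3L) {
    triples <- list()
    for (a in wls) for (b in wls) for (c0 in wls) {
      if (length(unique(c(a, b, c0))) == 3L) triples[[length(triples) + 1L]] <- c(a, b, c0)
    }
    out$RA <- pick("RA", triples)
  } else {
    warning("RA skipped: fewer than 3 selected bands")
  }
  out
}

#' Per-tree LiDAR canopy metrics
#'
#' Computes the 10-metric record (5 height + 5 intensity metrics) on the
#' points above `height_threshold`:
#' \itemize{
#'   \item `elev_percentile_{10,20,25,30}th`: linear-interpolation
#'     percentiles of z.
#'   \item `elev_AIH_5th`: accumulated-interval-height percentile -- the
#'     smallest z (ascending) at which the running sum of z reaches 5\% of
#'     the total z sum; sensitive to lower-crown point loss.
#'   \item `int_mean`, `int_std`, `int_skewness`, `int_kurtosis` (excess,
#'     Gaussian -> 0), `int_p50` of intensity.
#' }
#'
#' @param cloud A `tree_cloud`.
#' @param height_threshold Points at or below this height (m) are excluded.
#' @return Named list of class `lidar_metrics` with the 10 metrics.
#' @export
lidar_metrics <- function(cloud, height_threshold = 0.5) {
  stopifnot(inherits(cloud, "data.frame"))
  keep <- cloud$z > height_threshold
  z <- cloud$z[keep]
  intens <- cloud$intensity[keep]
  if (length(z) < 10L) {
    stop("insufficient points: need >= 10 above ", height_threshold, " m, found ",
         length(z), call. = FALSE)
  }
  m2 <- mean((intens - mean(intens))^2)
  m3 <- mean((intens - mean(intens))^3)
  m4 <- mean((intens - mean(intens))^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0
  out <- list(
    elev_percentile_10th = unname(stats::quantile(z, 0.10, type = 7)),
    elev_percentile_20th = unname(stats::quantile(z, 0.20, type = 7)),
    elev_percentile_25th = unname(stats::quantile(z, 0.25, type = 7)),
    elev_percentile_30th = unname(stats::quantile(z, 0.30, type = 7)),
    elev_AIH_5th = aih_percentile(z, 5),
    int_mean = mean(intens),
    int_std = stats::sd(intens),
    int_skewness = skew,
    int_kurtosis = kurt,
    int_p50 = unname(stats::median(intens))
  )
  class(out) <- c("lidar_metrics", "list")
  out
}

#' Accumulated-interval-height percentile
#'
#' The smallest height z (in ascending order) at which the running sum of
#' heights reaches p\% of the total height sum. Unlike an ordinary
#' percentile it weights points by their height, so it reacts strongly to
#' loss of low points; it is not translation-equivariant.
#'
#' @param z Heights (m), all > 0 after filtering.
#' @param p Percentage in (0, 100\].
#' @return Height in m.
#' @export
aih_percentile <- function(z, p) {
  if (length(z) == 0L) stop("empty height vector", call. = FALSE)
  if (p <= 0 || p > 100) stop("`p` must be in (0, 100]", call. = FALSE)
  zs <- sort(z)
  cs <- cumsum(zs)
  zs[which(cs >= p / 100 * cs[length(cs)])[1]]
}

#' Assemble the per-tree feature table
#'
#' Joins vegetation-index values with LiDAR metrics, one row per tree.
#' Trees whose cloud has too few filtered points are dropped with a warning.
#'
#' @param spectra A `spectra_table`.
#' @param clouds Named list of `tree_cloud`s keyed by `tree_id` (order must
#'   cover the spectra's trees).
#' @param vi_defs List of `vi_definition`s (e.g. from [vi_search()]).
#' @param height_threshold Passed to [lidar_metrics()].
#' @return A `feature_table` data.frame: `tree_id`, `stage`, VI columns
#'   named by [vi_name()], then the 10 LiDAR metric columns. VI column
#'   names are recorded in `attr(, "vi_cols")`, LiDAR names in
#'   `attr(, "lidar_cols")`.
#' @export
build_feature_table <- function(spectra, clouds, vi_defs, height_threshold = 0.5) {
  sm <- spectra_matrix(spectra)
  vi_mat <- vapply(vi_defs, function(d) compute_vi(spectra, d), numeric(nrow(spectra)))
  colnames(vi_mat) <- vapply(vi_defs, vi_name, character(1))

  metric_names <- c("elev_percentile_10th", "elev_percentile_20th",
                    "elev_percentile_25th", "elev_percentile_30th", "elev_AIH_5th",
                    "int_mean", "int_std", "int_skewness", "int_kurtosis", "int_p50")
  rows <- vector("list", nrow(spectra))
  ok <- logical(nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    id <- spectra$tree_id[i]
    cl <- clouds[[id]]
    if (is.null(cl)) {
      warning("no point cloud for tree ", id, "; dropped")
      next
    }
    met <- tryCatch(lidar_metrics(cl, height_threshold), error = function(e) NULL)
    if (is.null(met)) {
      warning("tree ", id, " has too few filtered points; dropped")
      next
    }
    rows[[i]] <- unlist(met[metric_names])
    ok[i] <- TRUE
  }
  lidar_mat <- do.call(rbind, rows[ok])
  out <- data.frame(tree_id = spectra$tree_id[ok], stage = spectra$stage[ok],
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(vi_mat[ok, , drop = FALSE], check.names = FALSE),
               as.data.frame(lidar_mat, check.names = FALSE))
  attr(out, "vi_cols") <- colnames(vi_mat)
  attr(out, "lidar_cols") <- metric_names
  class(out) <- c("feature_table", "data.frame")
  out
}
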