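#' Damage stage from defoliation percentage
#'
#' Trees are staged by defoliation percentage (DP): mild for DP <= 30,
#' moderate for 30 < DP < 50, severe for DP >= 50. Mild is the "early"
#' detection class.
#'
#' @param dp Numeric vector of defoliation percentages in \[0, 100\].
#' @return Ordered factor with levels `mild < moderate < severe`.
#' @export
#' @examples
#' stage_from_dp(c(10, 40, 75))
stage_from_dp <- function(dp) {
  if (!is.numeric(dp) || any(!is.finite(dp)) || any(dp < 0 | dp > 100)) {
    stop("`dp` must be finite and within [0, 100]", call. = FALSE)
  }
  out <- ifelse(dp <= 30, "mild", ifelse(dp < 50, "moderate", "severe"))
  factor(out, levels = damage_stages(), ordered = TRUE)
}

#' @rdname stage_from_dp
#' @export
damage_stages <- function() c("mild", "moderate", "severe")

#' Configuration for the synthetic spectra generator
#'
#' Defaults follow the study design the generator emulates: 103/99/82 trees
#' in the mild/moderate/severe stages and 145 bands evenly spaced on
#' 400--1000 nm. Effect sizes are expressed per unit DP: a tree at DP = 60
#' gains `60 * red_edge_gain` reflectance (before windowing) in the red
#' edge and loses `60 * nir_loss` in the NIR plateau.
#'
#' @param n_per_class Integer vector of 3 class sizes (mild, moderate, severe).
#' @param n_bands Number of bands on the evenly spaced 400--1000 nm grid.
#' @param red_edge_gain Reflectance gain per unit DP in the 680--760 nm window.
#' @param nir_loss Reflectance loss per unit DP in the 900--1000 nm window.
#' @param smooth_noise_sd Std. dev. of the smooth correlated noise component
#'   (reflectance units); set 0 to disable.
#' @param smooth_noise_scale Length-scale (nm) of the smooth noise component.
#' @param white_noise_sd Std. dev. of independent per-band noise; 0 disables.
#' @param seed Integer seed; the dataset is reproducible from it.
#' @return A list of class `spectra_config`.
#' @export
spectra_config <- function(n_per_class = c(103L, 99L, 82L),
                           n_bands = 145L,
                           red_edge_gain = 0.0012,
                           nir_loss = 0.0010,
                           smooth_noise_sd = 0.010,
                           smooth_noise_scale = 60,
                           white_noise_sd = 0.004,
                           seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || any(n_per_class < 1L)) {
    stop("`n_per_class` must be 3 counts >= 1", call. = FALSE)
  }
  if (n_bands < 2L) stop("`n_bands` must be >= 2", call. = FALSE)
  sds <- c(smooth_noise_sd, white_noise_sd)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0", call. = FALSE)
  if (smooth_noise_scale <= 0) stop("`smooth_noise_scale` must be > 0", call. = FALSE)
  structure(list(
    n_per_class = n_per_class,
    wavelengths = seq(400, 1000, length.out = as.integer(n_bands)),
    red_edge_gain = red_edge_gain,
    nir_loss = nir_loss,
    smooth_noise_sd = smooth_noise_sd,
    smooth_noise_scale = smooth_noise_scale,
    white_noise_sd = white_noise_sd,
    seed = as.integer(seed)
  ), class = "spectra_config")
}

#' Healthy conifer canopy reflectance template
#'
#' Smooth template with the canonical features of a green conifer canopy:
#' chlorophyll absorption wells near 450 and 670 nm, a green reflectance
#' peak near 550 nm, the red-edge ramp between 680 and 760 nm, a NIR
#' plateau, and a weak water absorption dip near 970 nm.
#'
#' @param wavelengths Strictly increasing grid in nm, within \[350, 1100\].
#' @return Reflectance vector in (0, 1), same length as `wavelengths`.
#' @export
#' @examples
#' r <- base_spectrum(seq(400, 1000, length.out = 145))
base_spectrum <- function(wavelengths) {
  if (length(wavelengths) == 0L) stop("empty wavelength grid", call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(wavelengths < 350 | wavelengths > 1100)) {
    stop("wavelengths must lie within [350, 1100] nm", call. = FALSE)
  }
  if (is.unsorted(wavelengths, strictly = TRUE) && length(wavelengths) > 1L) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  wl <- wavelengths
  r <- 0.04 + 0.41 / (1 + exp(-(wl - 715) / 11)) +      # red-edge ramp to NIR plateau
    0.045 * exp(-(wl - 552)^2 / (2 * 22^2)) -           # green peak
    0.012 * exp(-(wl - 668)^2 / (2 * 14^2)) -           # red chlorophyll well
    0.015 * exp(-(wl - 455)^2 / (2 * 20^2)) -           # blue chlorophyll well
    0.035 * exp(-(wl - 972)^2 / (2 * 18^2))             # water dip
  pmin(pmax(r, 1e-4), 1 - 1e-4)
}

# smooth windows carrying the defoliation response
.red_edge_window <- function(wl) exp(-(wl - 715)^2 / (2 * 34^2))
.nir_window <- function(wl) 1 / (1 + exp(-(wl - 895) / 12))

#' Impose a defoliation response on a reflectance spectrum
#'
#' Progressive needle loss raises red-edge reflectance (blue shift of the
#' red edge) and lowers NIR reflectance (water/biomass loss, e.g. near
#' 926 nm). The deterministic response is monotone in DP band-wise: with
#' noise off, reflectance in 680--760 nm is non-decreasing and in
#' 900--1000 nm non-increasing in `dp`.
#'
#' @param base Reflectance vector on the config's wavelength grid.
#' @param dp Defoliation percentage in \[0, 100\].
#' @param cfg A [spectra_config()].
#' @param noise If `TRUE`, add the smooth + white noise components (uses the
#'   current RNG state; seed management belongs to the caller).
#' @return Reflectance vector clipped to \[0, 1\].
#' @export
apply_defoliation <- function(base, dp, cfg = spectra_config(), noise = FALSE) {
  if (!is.numeric(dp) || length(dp) != 1L || !is.finite(dp) || dp < 0 || dp > 100) {
    stop("`dp` must be a single value in [0, 100]", call. = FALSE)
  }
  wl <- cfg$wavelengths
  if (length(base) != length(wl)) {
    stop("`base` length does not match the config wavelength grid", call. = FALSE)
  }
  r <- base +
    dp * cfg$red_edge_gain * .red_edge_window(wl) -
    dp * cfg$nir_loss * .nir_window(wl)
  if (noise) {
    r <- r + .smooth_noise(wl, cfg$smooth_noise_sd, cfg$smooth_noise_scale) +
      stats::rnorm(length(wl), 0, cfg$white_noise_sd)
    # keep reflectance physically positive so ratio indices stay defined
    r <- pmax(r, 1e-6)
  }
  pmin(pmax(r, 0), 1)
}

# correlated noise: mixture of Gaussian bumps with the configured length-scale,
# scaled so the marginal sd per band is ~sd
.smooth_noise <- function(wl, sd, scale) {
  if (sd <= 0) return(numeric(length(wl)))
  n_bumps <- max(4L, ceiling(diff(range(wl)) / scale) + 2L)
  centers <- stats::runif(n_bumps, min(wl) - scale, max(wl) + scale)
  amps <- stats::rnorm(n_bumps)
  basis <- vapply(centers, function(c0) exp(-(wl - c0)^2 / (2 * scale^2)), numeric(length(wl)))
  raw <- drop(basis %*% amps)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) return(numeric(length(wl)))
  raw / s * sd
}

# per-stage DP sampling intervals: uniform away from degenerate boundaries
.dp_intervals <- list(mild = c(5, 30), moderate = c(30, 50), severe = c(50, 90))

#' Generate a synthetic per-tree canopy spectra dataset
#'
#' Draws DP uniformly within each stage's interval (mild 5--30,
#' moderate 30--50 open, severe 50--90), applies the defoliation response
#' to the healthy template and adds the configured noise. Reproducible
#' from `cfg$seed`.
#'
#' @param cfg A [spectra_config()].
#' @return A `spectra_table`: data.frame with columns `tree_id`, `stage`,
#'   `dp`, then one reflectance column per band named by wavelength
#'   (2 decimals); wavelengths stored in `attr(, "wavelengths")`.
#' @export
#' @examples
#' st <- generate_spectra_dataset(spectra_config(n_per_class = c(8, 8, 8)))
#' table(st$stage)
generate_spectra_dataset <- function(cfg = spectra_config()) {
  stopifnot(inherits(cfg, "spectra_config"))
  set.seed(cfg$seed)
  wl <- cfg$wavelengths
  base <- base_spectrum(wl)
  stages <- damage_stages()
  n_total <- sum(cfg$n_per_class)
  dp <- numeric(n_total)
  stage <- character(n_total)
  idx <- 0L
  for (k in seq_along(stages)) {
    n_k <- cfg$n_per_class[k]
    iv <- .dp_intervals[[stages[k]]]
    # open interval for moderate: keep draws strictly inside (30, 50)
    eps <- if (stages[k] == "moderate") 1e-6 else 0
    dp[idx + seq_len(n_k)] <- stats::runif(n_k, iv[1] + eps, iv[2] - eps)
    stage[idx + seq_len(n_k)] <- stages[k]
    idx <- idx + n_k
  }
  refl <- t(vapply(dp, function(d) apply_defoliation(base, d, cfg, noise = TRUE),
                   numeric(length(wl))))
  colnames(refl) <- sprintf("%.2f", wl)
  out <- data.frame(
    tree_id = sprintf("tree_%03d", seq_len(n_total)),
    stage = factor(stage, levels = stages, ordered = TRUE),
    dp = dp,
    check.names = FALSE
  )
  out <- cbind(out, as.data.frame(refl, check.names = FALSE))
  attr(out, "wavelengths") <- wl
  class(out) <- c("spectra_table", "data.frame")
  out
}

#' Configuration for the synthetic crown point-cloud generator
#'
#' Models a conical conifer crown sampled at a fixed ground-projected pulse
#' density. Defoliation removes a DP-proportional fraction of crown points
#' with removal probability biased toward the lower crown (the pest feeds
#' from the bottom up), and return intensity declines and grows more
#' heterogeneous with DP.
#'
#' @param crown_height Mean crown length in m (crown base to apex).
#' @param crown_height_sd Tree-to-tree sd of crown length, m.
#' @param crown_base Mean height of the crown base above ground, m.
#' @param crown_base_sd Tree-to-tree sd of the crown base height, m.
#' @param crown_radius Mean crown radius at the base, m.
#' @param crown_radius_sd Tree-to-tree sd of the crown radius, m.
#' @param density Ground-projected point density, points per m^2.
#' @param removal_bias Exponent of the lower-crown removal weighting;
#'   0 gives uniform removal.
#' @param intensity_mean,intensity_sd Base return intensity (8-bit-like
#'   0--255 scale) for an undamaged tree and its within-crown sd.
#' @param intensity_tree_sd Tree-to-tree sd of the mean intensity
#'   (sensor/incidence-angle variability between crowns).
#' @param intensity_dp_slope Intensity decline per unit DP.
#' @param intensity_dp_spread Relative growth of intensity sd per unit DP.
#' @param seed Integer seed.
#' @return A list of class `crown_config`.
#' @export
crown_config <- function(crown_height = 5,
                         crown_height_sd = 0.6,
                         crown_base = 1.5,
                         crown_base_sd = 0.3,
                         crown_radius = 1.5,
                         crown_radius_sd = 0.2,
                         density = 189,
                         removal_bias = 2,
                         intensity_mean = 160,
                         intensity_sd = 18,
                         intensity_tree_sd = 10,
                         intensity_dp_slope = 0.6,
                         intensity_dp_spread = 0.006,
                         seed = 1L) {
  if (density <= 0) stop("`density` must be > 0", call. = FALSE)
  if (crown_height <= 0 || crown_radius <= 0) {
    stop("crown dimensions must be > 0", call. = FALSE)
  }
  if (any(c(crown_height_sd, crown_base_sd, crown_radius_sd, intensity_tree_sd) < 0)) {
    stop("tree-to-tree standard deviations must be >= 0", call. = FALSE)
  }
  if (removal_bias < 0) stop("`removal_bias` must be >= 0", call. = FALSE)
  structure(list(
    crown_height = crown_height, crown_height_sd = crown_height_sd,
    crown_base = crown_base, crown_base_sd = crown_base_sd,
    crown_radius = crown_radius, crown_radius_sd = crown_radius_sd,
    density = density,
    removal_bias = removal_bias,
    intensity_mean = intensity_mean, intensity_sd = intensity_sd,
    intensity_tree_sd = intensity_tree_sd,
    intensity_dp_slope = intensity_dp_slope,
    intensity_dp_spread = intensity_dp_spread,
    seed = as.integer(seed)
  ), class = "crown_config")
}

#' Generate a synthetic defoliated crown point cloud
#'
#' A full conical crown is sampled first; a fraction `dp/100` of its points
#' is then removed by per-point Bernoulli draws whose probabilities are
#' weighted toward low heights by `cfg$removal_bias` (mean removal
#' probability equals `dp/100`). Intensities are Gaussian with mean
#' decreasing and spread increasing in DP, clipped to \[0, 255\].
#'
#' @param dp Defoliation percentage in \[0, 100\].
#' @param cfg A [crown_config()].
#' @param tree_id Identifier stored on the cloud.
#' @return A `tree_cloud`: data.frame with columns `x`, `y`, `z`
#'   (ground-normalized m, all >= 0) and `intensity`; full-crown point
#'   count in `attr(, "n_full")`.
#' @export
generate_tree_cloud <- function(dp, cfg = crown_config(), tree_id = "tree_001") {
  if (!is.numeric(dp) || length(dp) != 1L || !is.finite(dp) || dp < 0 || dp > 100) {
    stop("`dp` must be a single value in [0, 100]", call. = FALSE)
  }
  stopifnot(inherits(cfg, "crown_config"))
  set.seed(cfg$seed)
  # tree-level variability: crown dimensions and mean return intensity
  height <- max(1, stats::rnorm(1, cfg$crown_height, cfg$crown_height_sd))
  base_z <- max(0.6, stats::rnorm(1, cfg$crown_base, cfg$crown_base_sd))
  radius <- max(0.3, stats::rnorm(1, cfg$crown_radius, cfg$crown_radius_sd))
  tree_offset <- stats::rnorm(1, 0, cfg$intensity_tree_sd)
  n_full <- max(20L, round(cfg$density * pi * radius^2))
  # relative height in the crown; denser foliage toward the base of a cone
  u <- stats::rbeta(n_full, 1.4, 1.8)
  z <- base_z + u * height
  r_at <- radius * (1 - u)                      # conical taper
  rho <- sqrt(stats::runif(n_full)) * pmax(r_at, 0.05)
  theta <- stats::runif(n_full, 0, 2 * pi)
  x <- rho * cos(theta)
  y <- rho * sin(theta)

  keep <- rep(TRUE, n_full)
  if (dp > 0) {
    w <- (1 - u)^cfg$removal_bias               # heavier removal low in the crown
    p_rm <- dp / 100 * w / mean(w)
    p_rm <- pmin(pmax(p_rm, 0), 1)
    keep <- stats::runif(n_full) >= p_rm
    if (!any(keep)) keep[which.max(z)] <- TRUE  # never return an empty cloud
  }
  n_kept <- sum(keep)
  sd_dp <- cfg$intensity_sd * (1 + cfg$intensity_dp_spread * dp)
  intensity <- stats::rnorm(n_kept,
                            cfg$intensity_mean + tree_offset - cfg$intensity_dp_slope * dp,
                            sd_dp)
  intensity <- pmin(pmax(intensity, 0), 255)
  out <- data.frame(x = x[keep], y = y[keep], z = z[keep], intensity = intensity)
  attr(out, "tree_id") <- tree_id
  attr(out, "n_full") <- n_full
  class(out) <- c("tree_cloud", "data.frame")
  out
}
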