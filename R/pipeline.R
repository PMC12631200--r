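#' Default pipeline configuration
#'
#' One root seed fans out deterministically to per-stage seeds (spectra,
#' clouds, band selection CV, split, forests), so any stage can be rerun in
#' isolation and reproduce the full run's numbers.
#'
#' @param seed Root seed.
#' @param n_per_class Class sizes for the simulated stand.
#' @param method Band-selection route: `"isic-spa"`, `"spa"`, `"isic"`, or
#'   `"fixed"` (use `bands` as given, skipping selection).
#' @param bands Wavelengths (nm) used when `method = "fixed"`; defaults to
#'   the red-edge/NIR trio 686, 759, 926.
#' @param k_max Largest SPA subset size.
#' @param n_starts Number of SPA start bands (evenly spaced subsample;
#'   `NULL` launches from every band).
#' @param split_ratio Train fraction.
#' @param folds CV folds inside selection.
#' @param ntree_select Forest size inside wrapper selection.
#' @param ntree Forest size for the final models.
#' @param alpha Screening significance level.
#' @param out_dir Optional directory for stage artifacts (CSV/JSON).
#' @return A named list (class `run_config`).
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_class = c(103L, 99L, 82L),
                            method = c("isic-spa", "spa", "isic", "fixed"),
                            bands = c(686, 759, 926),
                            k_max = 10L,
                            n_starts = 15L,
                            split_ratio = 0.6,
                            folds = 10L,
                            ntree_select = 150L,
                            ntree = 500L,
                            alpha = 0.01,
                            out_dir = NULL) {
  method <- match.arg(method)
  if (split_ratio <= 0 || split_ratio >= 1) stop("`split_ratio` must be in (0, 1)", call. = FALSE)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 method = method, bands = bands, k_max = as.integer(k_max),
                 n_starts = if (is.null(n_starts)) NULL else as.integer(n_starts),
                 split_ratio = split_ratio, folds = as.integer(folds),
                 ntree_select = as.integer(ntree_select), ntree = as.integer(ntree),
                 alpha = alpha, out_dir = out_dir),
            class = "run_config")
}

# fixed fan-out of the root seed to stage seeds (kept < 2^31)
.stage_seeds <- function(seed) {
  base <- (as.integer(seed) %% 20000000L) * 100L
  list(spectra = base + 1L, clouds = base + 2L, select = base + 3L,
       split = base + 4L, rf = base + 5L, mda = base + 6L)
}

#' Run the full early-detection pipeline
#'
#' Simulate (or accept) per-tree spectra and crown clouds, select sensitive
#' bands, build vegetation indices and LiDAR metrics, screen features for
#' stage separability, and train/evaluate random-forest models on the
#' HSI-only, LiDAR-only and combined feature sets.
#'
#' @param config A [pipeline_config()] (or plain list with the same fields,
#'   e.g. from [read_run_config()]).
#' @param spectra Optional pre-built `spectra_table` (skips simulation).
#' @param clouds Optional named list of `tree_cloud`s keyed by tree id.
#' @return A `run_report`: list with `config`, `seeds`, `selection`,
#'   `vi_definitions`, `screening`, `reports` (classification reports for
#'   `hsi`, `lidar`, `combined`), `importance` (combined-model MDA), and
#'   `features` (the feature table).
#' @export
run_pipeline <- function(config = pipeline_config(), spectra = NULL, clouds = NULL) {
  if (!inherits(config, "run_config")) {
    config <- do.call(pipeline_config, config)
  }
  seeds <- .stage_seeds(config$seed)

  # --- simulate -------------------------------------------------------------
  if (is.null(spectra)) {
    scfg <- spectra_config(n_per_class = config$n_per_class, seed = seeds$spectra)
    spectra <- generate_spectra_dataset(scfg)
  }
  sm <- spectra_matrix(spectra)
  if (is.null(clouds)) {
    ccfg <- crown_config()
    clouds <- lapply(seq_len(nrow(spectra)), function(i) {
      ci <- ccfg
      ci$seed <- seeds$clouds + i
      generate_tree_cloud(spectra$dp[i], ci, tree_id = spectra$tree_id[i])
    })
    names(clouds) <- spectra$tree_id
  }

  # --- band selection (on the training portion only) ------------------------
  split <- stratified_split(sm$stage, ratio = config$split_ratio, seed = seeds$split)
  cvc <- cv_config(folds = config$folds, ntree = config$ntree_select,
                   seed = seeds$select)
  starts <- NULL
  if (!is.null(config$n_starts) && config$n_starts < ncol(sm$x)) {
    starts <- unique(round(seq(1, ncol(sm$x), length.out = config$n_starts)))
  }
  x_train <- sm$x[split$train, , drop = FALSE]
  y_train <- sm$stage[split$train]
  selection <- switch(config$method,
    "fixed" = {
      idx <- sort(unique(nearest_band(config$bands, sm$wavelengths)))
      structure(list(method = "fixed", selected = idx,
                     wavelengths = sm$wavelengths[idx], k = length(idx),
                     curve = NULL), class = "band_selection")
    },
    "spa" = spa_select(x_train, y_train, cv_cfg = cvc, k_max = config$k_max,
                       starts = starts, wavelengths = sm$wavelengths),
    "isic" = isic_select(x_train, y_train, cv_cfg = cvc,
                         wavelengths = sm$wavelengths),
    "isic-spa" = isic_spa_select(x_train, y_train, cv_cfg = cvc,
                                 k_max = config$k_max, starts = starts,
                                 wavelengths = sm$wavelengths))

  # --- features -------------------------------------------------------------
  vi_defs <- vi_search(spectra, selection$wavelengths)
  features <- build_feature_table(spectra, clouds, vi_defs)

  # --- screening ------------------------------------------------------------
  screening <- screen_features(features, alpha = config$alpha)
  retained <- screening$feature[screening$retained]
  vi_cols <- intersect(attr(features, "vi_cols"), retained)
  lidar_cols <- intersect(attr(features, "lidar_cols"), retained)
  if (length(vi_cols) == 0L) vi_cols <- attr(features, "vi_cols")
  if (length(lidar_cols) == 0L) lidar_cols <- attr(features, "lidar_cols")

  # --- classify: HSI / LiDAR / combined ------------------------------------
  labels <- features$stage
  fsplit <- stratified_split(labels, ratio = config$split_ratio, seed = seeds$split)
  rfc <- rf_config(ntree = config$ntree, seed = seeds$rf)
  run_source <- function(cols) {
    fp <- fit_predict_rf(features[fsplit$train, cols, drop = FALSE],
                         labels[fsplit$train],
                         features[fsplit$test, cols, drop = FALSE], rfc)
    list(report = confusion_and_report(labels[fsplit$test], fp$pred,
                                       levels = damage_stages()),
         model = fp$model)
  }
  hsi <- run_source(vi_cols)
  lidar <- run_source(lidar_cols)
  combined <- run_source(c(vi_cols, lidar_cols))
  importance <- mda_importance(combined$model,
                               features[fsplit$test, c(vi_cols, lidar_cols), drop = FALSE],
                               labels[fsplit$test], seed = seeds$mda)

  report <- list(config = unclass(config), seeds = seeds,
                 selection = selection, vi_definitions = vi_defs,
                 screening = screening,
                 retained_features = list(vi = vi_cols, lidar = lidar_cols),
                 reports = list(hsi = hsi$report, lidar = lidar$report,
                                combined = combined$report),
                 importance = importance,
                 features = features)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) .write_run_artifacts(report, spectra, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Early-detection pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("Selected bands (", x$selection$method, "): ",
      paste(sprintf("%.1f", x$selection$wavelengths), collapse = ", "), " nm\n", sep = "")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-8s OA = %6.2f%%  Kappa = %.2f\n", nm, r$oa, r$kappa))
  }
  invisible(x)
}

.write_run_artifacts <- function(report, spectra, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(spectra, file.path(out_dir, "spectra.csv"))
  utils::write.csv(as.data.frame(report$features),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$screening),
                   file.path(out_dir, "screening.csv"), row.names = FALSE)
  json <- run_report_json(report)
  writeLines(json, file.path(out_dir, "run_report.json"))
  invisible(out_dir)
}

#' Serialize a run report to JSON (timestamps excluded, byte-stable)
#'
#' @param report A `run_report`.
#' @return A JSON string.
#' @export
run_report_json <- function(report) {
  rep_list <- function(r) list(oa = r$oa, kappa = r$kappa,
                               pa = as.list(r$pa), ua = as.list(r$ua),
                               confusion = unname(apply(r$confusion, 1, as.list)))
  payload <- list(
    seed = report$config$seed,
    method = report$selection$method,
    selected_wavelengths = report$selection$wavelengths,
    vi = lapply(report$vi_definitions, function(d)
      list(name = vi_name(d), rho = attr(d, "rho"))),
    retained_features = report$retained_features,
    reports = lapply(report$reports, rep_list),
    importance = report$importance
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
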