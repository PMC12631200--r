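#' Write a spectra table to CSV
#'
#' Comma-separated, UTF-8, dot decimal, mandatory header. Columns are
#' `tree_id`, `stage`, `dp`, then one reflectance column per band named by
#' its wavelength in nm rounded to 2 decimals.
#'
#' @param spectra A `spectra_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "data.frame"))
  utils::write.csv(as.data.frame(spectra), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectra table from CSV
#'
#' Validates the dialect written by [write_spectra()]: band columns are
#' named by wavelength and re-sorted to a strictly increasing grid if the
#' file carries them in another order. Non-numeric reflectance cells raise
#' an error naming the offending row and column.
#'
#' @param path CSV file path.
#' @param require_dp If `TRUE`, a `dp` column must be present; when present,
#'   stage labels are checked for consistency with DP.
#' @return A `spectra_table`.
#' @export
read_spectra <- function(path, require_dp = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  meta_cols <- c("tree_id", "stage", if (require_dp) "dp")
  missing <- setdiff(meta_cols, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  band_names <- setdiff(names(raw), c("tree_id", "stage", "dp"))
  wl <- suppressWarnings(as.numeric(band_names))
  if (length(band_names) == 0L || any(is.na(wl))) {
    bad <- band_names[is.na(wl)]
    stop("band columns must be named by wavelength; offending column(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  for (bn in band_names) {
    v <- raw[[bn]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        row <- which(is.na(num) & !is.na(v))[1]
        stop(sprintf("non-numeric reflectance at row %d, column '%s'", row, bn),
             call. = FALSE)
      }
      raw[[bn]] <- num
    }
    if (anyNA(raw[[bn]])) {
      stop(sprintf("missing reflectance at row %d, column '%s'",
                   which(is.na(raw[[bn]]))[1], bn), call. = FALSE)
    }
  }
  ord <- order(wl)
  wl <- wl[ord]
  if (anyDuplicated(wl)) stop("duplicated wavelength columns", call. = FALSE)
  refl <- raw[, band_names[ord], drop = FALSE]
  out <- data.frame(tree_id = as.character(raw$tree_id),
                    stage = factor(raw$stage, levels = damage_stages(), ordered = TRUE),
                    check.names = FALSE)
  if (anyNA(out$stage)) {
    stop("unknown stage label at row ", which(is.na(out$stage))[1], call. = FALSE)
  }
  if ("dp" %in% names(raw)) {
    out$dp <- as.numeric(raw$dp)
    if (!all(out$stage == stage_from_dp(out$dp))) {
      stop("stage labels inconsistent with dp at row ",
           which(out$stage != stage_from_dp(out$dp))[1], call. = FALSE)
    }
  }
  out <- cbind(out, refl)
  attr(out, "wavelengths") <- wl
  class(out) <- c("spectra_table", "data.frame")
  out
}

#' Extract the reflectance matrix and wavelength grid from a spectra table
#'
#' @param spectra A `spectra_table`.
#' @return List with `x` (trees x bands matrix), `wavelengths`, `stage`,
#'   and `dp` (NULL if absent).
#' @export
spectra_matrix <- function(spectra) {
  wl <- attr(spectra, "wavelengths")
  if (is.null(wl)) {
    bn <- setdiff(names(spectra), c("tree_id", "stage", "dp"))
    wl <- as.numeric(bn)
  }
  bn <- sprintf("%.2f", wl)
  if (!all(bn %in% names(spectra))) {
    bn <- setdiff(names(spectra), c("tree_id", "stage", "dp"))
  }
  x <- as.matrix(spectra[, bn, drop = FALSE])
  rownames(x) <- spectra$tree_id
  list(x = x, wavelengths = wl, stage = spectra$stage,
       dp = if ("dp" %in% names(spectra)) spectra$dp else NULL)
}

#' Write a tree point cloud as XYZI text
#'
#' Four whitespace-separated float columns: x, y, z, intensity. No header.
#'
#' @param cloud A `tree_cloud`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "data.frame"))
  utils::write.table(cloud[, c("x", "y", "z", "intensity")], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tree point cloud from XYZI text
#'
#' Expects >= 4 whitespace-separated numeric columns (x, y, z, intensity);
#' a 3-column file is rejected. An empty file yields an empty cloud, which
#' downstream metric computation will refuse.
#'
#' @param path XYZI text file path.
#' @param tree_id Identifier stored on the cloud (defaults to the file name).
#' @return A `tree_cloud`.
#' @export
read_cloud <- function(path, tree_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(tree_id)) tree_id <- sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      intensity = numeric(0))
  } else {
    raw <- utils::read.table(path, header = FALSE)
    if (ncol(raw) < 4L) {
      stop("XYZI file must have >= 4 columns, found ", ncol(raw), ": ", path,
           call. = FALSE)
    }
    raw <- raw[, 1:4]
    names(raw) <- c("x", "y", "z", "intensity")
    if (!all(vapply(raw, is.numeric, logical(1)))) {
      stop("non-numeric values in point cloud file: ", path, call. = FALSE)
    }
    if (any(!is.finite(as.matrix(raw)))) {
      stop("non-finite coordinates in point cloud file: ", path, call. = FALSE)
    }
    out <- raw
  }
  attr(out, "tree_id") <- tree_id
  class(out) <- c("tree_cloud", "data.frame")
  out
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path.
#' @return A named list, validated by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
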