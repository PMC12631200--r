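#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over the standard Kruskal-Wallis implementation (mid-ranks
#' with tie correction, chi-square approximation on groups - 1 degrees of
#' freedom), with one convention layered on: when every value in every
#' group is identical the test is returned as H = 0, p = 1 rather than an
#' error.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values;
#'   total n >= 5.
#' @return List with `H` (statistic) and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  if (sum(sizes) < 5L) stop("total sample size must be >= 5", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Screen features for damage-stage separability
#'
#' A feature is retained iff (a) the overall Kruskal-Wallis test across all
#' three stages and (b) the pairwise mild-versus-moderate Kruskal-Wallis
#' test are both significant at `alpha`. The pairwise criterion is what
#' makes the screen an early-detection filter: a feature that only
#' separates the severe stage passes (a) but fails (b) and is dropped.
#' P-values are reported raw (no multiple-testing correction).
#'
#' @param features A `feature_table` (needs all three stages present).
#' @param alpha Significance level (default 0.01).
#' @param feature_cols Columns to screen (defaults to every non-id column).
#' @return A `screening_report` data.frame: per feature the overall H and
#'   p, the mild-vs-moderate p, and the retained flag.
#' @export
screen_features <- function(features, alpha = 0.01, feature_cols = NULL) {
  stopifnot(inherits(features, "data.frame"))
  stage <- features$stage
  present <- damage_stages() %in% as.character(unique(stage))
  if (!all(present)) {
    stop("stage(s) absent from the data: ",
         paste(damage_stages()[!present], collapse = ", "), call. = FALSE)
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), c("tree_id", "stage", "dp"))
  }
  res <- lapply(feature_cols, function(f) {
    v <- features[[f]]
    by_stage <- split(v, stage)[damage_stages()]
    overall <- kruskal_wallis(by_stage)
    pairwise <- kruskal_wallis(by_stage[c("mild", "moderate")])
    data.frame(feature = f, H = overall$H, p_overall = overall$p,
               p_mild_moderate = pairwise$p,
               retained = overall$p < alpha && pairwise$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_report", "data.frame")
  out
}
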