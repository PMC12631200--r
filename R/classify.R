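#' Random-forest settings
#'
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed for the forest (default 42).
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(ntree = 500L, seed = 42L) {
  if (ntree < 1L) stop("`ntree` must be >= 1", call. = FALSE)
  structure(list(ntree = as.integer(ntree), seed = as.integer(seed)),
            class = "rf_config")
}

# nearest integer with .5 rounding away from the floor (not banker's rounding)
.round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Per class, the train count is the nearest integer to `ratio` times the
#' class size; the test set is the complement. Shuffling within class is
#' controlled by `seed`, so the plan is deterministic.
#'
#' @param labels Class labels (every class needs >= 2 samples).
#' @param ratio Train fraction in (0, 1) (default 0.6, a 6:4 split).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (disjoint, covering).
#' @export
stratified_split <- function(labels, ratio = 0.6, seed = 42L) {
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("class '", names(counts)[which(counts < 2L)[1]], "' has < 2 samples",
         call. = FALSE)
  }
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    n_train <- .round_half_up(ratio * length(idx))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)  # keep both sides non-empty
    train <- c(train, sample(idx)[seq_len(n_train)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Fit a random forest and predict on a test set
#'
#' Standard random-forest classifier (square-root feature subsampling),
#' configured with tree count and seed from `cfg`.
#'
#' @param train_x Training features (data.frame or matrix, no missing values).
#' @param train_y Training labels (>= 2 classes).
#' @param test_x Test features with the same columns.
#' @param cfg An [rf_config()].
#' @return List with `pred` (factor over the training levels) and `model`.
#' @export
fit_predict_rf <- function(train_x, train_y, test_x, cfg = rf_config()) {
  train_y <- factor(train_y)
  if (nlevels(droplevels(train_y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (anyNA(train_x) || anyNA(test_x)) stop("missing values in features", call. = FALSE)
  train_x <- as.data.frame(train_x)
  test_x <- as.data.frame(test_x)[, names(train_x), drop = FALSE]
  set.seed(cfg$seed)
  model <- randomForest::randomForest(x = train_x, y = droplevels(train_y),
                                      ntree = cfg$ntree)
  pred <- stats::predict(model, test_x)
  list(pred = factor(as.character(pred), levels = levels(train_y)), model = model)
}

#' Confusion matrix and accuracy report
#'
#' Builds the confusion matrix N (rows = true class, columns = predicted)
#' and derives overall accuracy OA = 100 trace/total, Cohen's Kappa
#' (p_o - p_e)/(1 - p_e) with p_e from row/column marginals, per-class
#' producer's accuracy PA_i = 100 N_ii / rowsum_i (recall) and user's
#' accuracy UA_j = 100 N_jj / colsum_j (precision). Percentages are kept
#' at full precision; rounding is presentation-only.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same length).
#' @param levels Class order (defaults to the damage stages when all labels
#'   are stages, otherwise the sorted union).
#' @return A `classification_report`: list with `confusion`, `oa`, `kappa`,
#'   `pa`, `ua`, `mean_pa`, `mean_ua`, `n`.
#' @export
confusion_and_report <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(levels)) {
    u <- union(y_true, y_pred)
    levels <- if (all(u %in% damage_stages())) damage_stages() else sort(u)
  }
  if (!all(c(y_true, y_pred) %in% levels)) {
    stop("labels outside the class set", call. = FALSE)
  }
  cm <- table(factor(y_true, levels = levels), factor(y_pred, levels = levels))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  n <- sum(cm)
  oa <- 100 * sum(diag(cm)) / n
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  pa <- 100 * diag(cm) / rowSums(cm)
  ua <- 100 * diag(cm) / colSums(cm)
  structure(list(confusion = cm, oa = oa, kappa = kappa,
                 pa = pa, ua = ua,
                 mean_pa = mean(pa, na.rm = TRUE),
                 mean_ua = mean(ua, na.rm = TRUE), n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("OA = %.2f%%, Kappa = %.2f (n = %d)\n", x$oa, x$kappa, x$n))
  cat(sprintf("mean PA = %.2f%%, mean UA = %.2f%%\n", x$mean_pa, x$mean_ua))
  print(x$confusion)
  invisible(x)
}

# deterministic stratified fold assignment
.stratified_folds <- function(labels, folds, seed) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("class '", names(counts)[which(counts < folds)[1]],
         "' has fewer samples than folds", call. = FALSE)
  }
  set.seed(seed)
  assignment <- integer(length(labels))
  for (lev in levels(labels)) {
    idx <- sample(which(labels == lev))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Mean stratified k-fold cross-validated accuracy
#'
#' @param x Features (data.frame or matrix).
#' @param labels Class labels; every class needs >= `folds` samples.
#' @param folds Number of folds (default 10).
#' @param rf_cfg An [rf_config()].
#' @param seed Seed for the fold assignment.
#' @return Mean of the per-fold accuracies (in \[0, 1\]).
#' @export
cross_val_accuracy <- function(x, labels, folds = 10L, rf_cfg = rf_config(),
                               seed = 42L) {
  x <- as.data.frame(x)
  labels <- factor(labels)
  fold_of <- .stratified_folds(labels, folds, seed)
  accs <- vapply(seq_len(folds), function(f) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    pred <- fit_predict_rf(x[tr, , drop = FALSE], labels[tr],
                           x[te, , drop = FALSE], rf_cfg)$pred
    mean(as.character(pred) == as.character(labels[te]))
  }, numeric(1))
  mean(accs)
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each feature, the evaluation-set accuracy drop after permuting that
#' feature's values, averaged over `n_repeats` seeded permutations. This is
#' the mean-decrease-accuracy estimand evaluated on an explicit held-out
#' set rather than per-tree out-of-bag samples.
#'
#' @param model A fitted classifier accepted by `predict()`.
#' @param x Evaluation features (>= 2 columns).
#' @param y Evaluation labels.
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return Data.frame with `feature`, `importance` (mean accuracy drop) and
#'   `sd` (dispersion over repeats), sorted by decreasing importance.
#' @export
mda_importance <- function(model, x, y, n_repeats = 10L, seed = 42L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need >= 2 features", call. = FALSE)
  y <- as.character(y)
  baseline <- mean(as.character(stats::predict(model, x)) == y)
  set.seed(seed)
  res <- lapply(names(x), function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[[f]] <- sample(xp[[f]])
      baseline - mean(as.character(stats::predict(model, xp)) == y)
    }, numeric(1))
    data.frame(feature = f, importance = mean(drops), sd = stats::sd(drops),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$importance), ]
}
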