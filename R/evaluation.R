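# Evaluation: classification report on the reduced feature set, ordinal
# accuracy with a distance-penalty reward, normalised confusion matrix with
# an underperformance warning, and stratified chi-squared stage separation.

#' Distance-penalty reward matrix
#'
#' `R(i, j) = 1 - |i - j| / (K_c - 1)` for true class `i` and predicted class
#' `j` on an ordinal scale: exact matches earn 1, the farthest corner
#' misclassifications earn 0.
#'
#' @param K_c Number of ordered classes (>= 2).
#' @return A `K_c` x `K_c` symmetric matrix with unit diagonal.
#' @export
reward_matrix <- function(K_c) {
  if (K_c < 2L)
    eb_abort("eb_config_error", "the reward matrix needs at least 2 classes")
  i <- seq_len(K_c)
  1 - abs(outer(i, i, `-`)) / (K_c - 1)
}

#' Ordinal accuracy
#'
#' Confusion-matrix accuracy weighted by the ordinal reward:
#' `(1/N) * sum_ij R(i, j) * C(i, j)` with `N` the total sample count. Equals
#' plain accuracy when all errors land in the farthest corner, and upper-
#' bounds it otherwise because near misses earn partial reward.
#'
#' @param C Square confusion matrix of raw counts (rows = true class).
#' @param R Reward matrix from [reward_matrix()]; defaults to the matching
#'   distance-penalty matrix.
#' @return Scalar in `[0, 1]`.
#' @export
ordinal_accuracy <- function(C, R = reward_matrix(nrow(C))) {
  stopifnot(nrow(C) == ncol(C), all(C >= 0))
  N <- sum(C)
  if (N == 0) eb_abort("eb_config_error", "empty confusion matrix")
  sum(R * C) / N
}

#' Row-normalised confusion matrix with underperformance warning
#'
#' Normalises each row of the confusion matrix to sum to 1 and computes the
#' mean of the diagonal (the mean per-class classification rate). A warning
#' of class `eb_performance_warning` is emitted if and only if that mean is
#' strictly below 0.75. Empty rows are excluded from the mean with a warning.
#'
#' @param C Square confusion matrix of raw counts.
#' @param threshold Warning threshold (default 0.75, strict).
#' @return List with `matrix` (row-normalised), `mean_diagonal`, and
#'   `warned` (logical).
#' @export
normalized_confusion <- function(C, threshold = 0.75) {
  stopifnot(nrow(C) == ncol(C))
  rs <- rowSums(C)
  empty <- rs == 0
  if (any(empty))
    eb_warning("eb_data_warning", paste0(
      "classes with no samples excluded from the diagonal mean: ",
      paste(rownames(C)[empty] %||% which(empty), collapse = ", ")))
  norm <- C / ifelse(rs == 0, 1, rs)
  mean_diag <- mean(diag(norm)[!empty])
  warned <- mean_diag < threshold
  if (warned)
    eb_warning("eb_performance_warning", sprintf(
      "mean per-class classification rate %.3f is below the expected %.2f",
      mean_diag, threshold))
  list(matrix = norm, mean_diagonal = mean_diag, warned = warned)
}

#' Cross-validated classification report on the reduced feature set
#'
#' Five-fold stratified cross-validation with a gradient-boosted tree
#' classifier on the cohort's (already feature-reduced) matrix. Reports
#' per-class precision, recall and F1 plus macro averages, the raw and
#' row-normalised confusion matrices, and ordinal accuracy. With three or
#' more classes, ordinal accuracy requires an explicit `outcome_order`;
#' otherwise it is skipped with a warning.
#'
#' @param cohort An `eb_cohort` restricted to the selected features.
#' @param features Optional further feature restriction.
#' @param seed Base seed; fold `i` uses `seed + i - 1`.
#' @param n_folds Number of folds (default 5).
#' @return An `eb_eval_report` list: `report` (data.frame), `confusion`,
#'   `normalized` (from [normalized_confusion()]), `ordinal_accuracy`
#'   (or `NA`).
#' @export
classification_report <- function(cohort, features = NULL, seed = 42L,
                                  n_folds = 5L) {
  if (!is.null(features)) cohort <- subset_cohort(cohort, features)
  X <- cohort$X
  lev <- cohort$outcome_order
  y <- factor(cohort$meta$Outcome, levels = lev)
  if (nlevels(droplevels(y)) < 2L)
    eb_abort("eb_config_error", "classification needs at least two classes")
  fold <- .stratified_folds(as.character(y), n_folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = lev)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    yf <- droplevels(y[tr])
    n_class <- nlevels(yf)
    freq <- table(yf)
    w <- as.numeric(length(yf[!is.na(yf)]) / (n_class * freq[yf]))
    seed_f <- seed + f - 1L
    set.seed(seed_f)
    params <- list(max_depth = 6L, eta = 0.3, nthread = 1L, seed = seed_f,
                   verbosity = 0L)
    label <- as.integer(yf) - 1L
    if (n_class == 2L) params$objective <- "binary:logistic"
    else { params$objective <- "multi:softprob"; params$num_class <- n_class }
    dm <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = label,
                               weight = w)
    fit <- xgboost::xgb.train(params = params, data = dm, nrounds = 100L)
    pr <- stats::predict(fit, X[!tr, , drop = FALSE])
    cls <- if (n_class == 2L) as.integer(pr > 0.5) + 1L
           else if (is.matrix(pr)) max.col(pr)
           else max.col(matrix(pr, ncol = n_class, byrow = TRUE))
    pred[!tr] <- levels(yf)[cls]
  }
  C <- table(true = y, predicted = pred)
  C <- unclass(C)
  precision <- diag(C) / pmax(colSums(C), 1)
  recall <- diag(C) / pmax(rowSums(C), 1)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  report <- data.frame(
    class = c(lev, "macro_avg"),
    precision = c(precision, mean(precision)),
    recall = c(recall, mean(recall)),
    f1 = c(f1, mean(f1)),
    support = c(rowSums(C), sum(C)),
    stringsAsFactors = FALSE, row.names = NULL)
  oa <- NA_real_
  if (length(lev) == 2L || isTRUE(cohort$explicit_order)) {
    oa <- ordinal_accuracy(C)
  } else {
    eb_warning("eb_data_warning",
               "no outcome order for >= 3 classes; ordinal accuracy skipped")
  }
  norm <- normalized_confusion(C)
  structure(list(report = report, confusion = C, normalized = norm,
                 ordinal_accuracy = oa),
            class = "eb_eval_report")
}

#' @method print eb_eval_report
#' @export
print.eb_eval_report <- function(x, ...) {
  cat("<eb_eval_report>\n")
  print(x$report, digits = 3)
  cat(sprintf("ordinal accuracy: %s\n",
              ifelse(is.na(x$ordinal_accuracy), "skipped",
                     sprintf("%.3f", x$ordinal_accuracy))))
  invisible(x)
}

#' Stratified chi-squared stage-separation test
#'
#' For every (subtype, outcome) stratum, tests the observed stage counts
#' against a uniform distribution over the stages occupied by that subtype
#' (goodness of fit, `dof = occupied stages - 1`). Strata with fewer than two
#' occupied stages are skipped with a note; strata with any expected count
#' below 1 are flagged unreliable. A significant result indicates that stage
#' assignment within the stratum is far from random.
#'
#' @param assignments MAP assignment table from [assign_subjects()].
#' @return Data.frame with one row per stratum: `subtype`, `outcome`, `n`,
#'   `occupied_stages`, `statistic`, `dof`, `p_value`, `unreliable`, `note`.
#' @export
chi2_stage_separation <- function(assignments) {
  out <- list()
  for (k in sort(unique(assignments$Subtype))) {
    sub <- assignments[assignments$Subtype == k, , drop = FALSE]
    occupied <- sort(unique(sub$Stage))
    for (oc in unique(sub$Outcome)) {
      cell <- sub[sub$Outcome == oc, , drop = FALSE]
      n <- nrow(cell)
      row <- data.frame(subtype = k, outcome = oc, n = n,
                        occupied_stages = length(occupied),
                        statistic = NA_real_, dof = NA_integer_,
                        p_value = NA_real_, unreliable = FALSE, note = "",
                        stringsAsFactors = FALSE)
      if (length(occupied) < 2L) {
        row$note <- "fewer than 2 occupied stages; test skipped"
      } else {
        obs <- tabulate(match(cell$Stage, occupied), length(occupied))
        expected <- n / length(occupied)
        row$statistic <- sum((obs - expected)^2 / expected)
        row$dof <- length(occupied) - 1L
        row$p_value <- stats::pchisq(row$statistic, row$dof,
                                     lower.tail = FALSE)
        if (expected < 1) {
          row$unreliable <- TRUE
          row$note <- "expected cell count below 1"
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
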