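# Ensemble stability-scored feature selection: three classifier families
# (gradient-boosted trees, penalised logistic regression, random forest)
# vote across five stratified folds; a feature's stability score is the
# fraction of the 15 (classifier, fold) top-K lists that contain it.

#' Selection configuration
#'
#' @param U_max Maximum number of features retained (hard cap 150).
#' @param n_folds Number of cross-validation folds (default 5).
#' @param stability_threshold Stability cutoff for retention (default 0.5,
#'   strict inequality).
#' @param base_seed Base random seed; fold `i` uses `base_seed + i - 1`.
#' @param activation_threshold Selection is skipped entirely for cohorts with
#'   fewer features than this (default 100).
#' @param top_k Optional override of the per-model candidate breadth K;
#'   `NULL` derives it with [determine_k()].
#' @return An `eb_selection_config` list.
#' @export
selection_config <- function(U_max = 150L, n_folds = 5L,
                             stability_threshold = 0.5, base_seed = 42L,
                             activation_threshold = 100L, top_k = NULL) {
  if (U_max < 1L || U_max > 150L)
    eb_abort("eb_config_error", "U_max must be in [1, 150] (hard cap 150)")
  structure(list(U_max = as.integer(U_max), n_folds = as.integer(n_folds),
                 stability_threshold = stability_threshold,
                 base_seed = as.integer(base_seed),
                 activation_threshold = as.integer(activation_threshold),
                 top_k = top_k),
            class = "eb_selection_config")
}

#' Candidate breadth K for per-model top lists
#'
#' `K = min(p, max(ceiling(0.05 * p), 3 * U_max))`: both 5% of the feature
#' count and three times the user's final cap act as floors on candidate
#' breadth (the tripling absorbs model-specific ranking noise), and K can
#' never exceed the number of features itself.
#'
#' @param p Total feature count.
#' @param U_max User maximum for the final feature set.
#' @return Integer K.
#' @export
determine_k <- function(p, U_max) {
  if (p < 1L) eb_abort("eb_config_error", "p must be at least 1")
  if (U_max < 1L || U_max > 150L)
    eb_abort("eb_config_error", "U_max must be in [1, 150]")
  as.integer(min(p, max(ceiling(0.05 * p), 3L * U_max)))
}

# Stratified fold ids (1..n_folds), deterministic given seed.
.stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Minimal SMOTE: synthesises minority-class samples by interpolating towards
# one of the k nearest same-class neighbours, until every class reaches the
# majority count. Applied to training folds only.
.smote <- function(X, y, k = 5L) {
  tab <- table(y)
  target <- max(tab)
  new_X <- list(); new_y <- character(0)
  for (cl in names(tab)) {
    need <- target - tab[[cl]]
    if (need <= 0) next
    idx <- which(y == cl)
    Xc <- X[idx, , drop = FALSE]
    if (length(idx) < 2L) {
      pick <- rep_len(seq_along(idx), need)
      new_X[[cl]] <- Xc[pick, , drop = FALSE]
    } else {
      d <- as.matrix(stats::dist(Xc))
      diag(d) <- Inf
      kk <- min(k, length(idx) - 1L)
      nn <- apply(d, 1L, function(r) order(r)[seq_len(kk)], simplify = FALSE)
      base <- sample(seq_along(idx), need, replace = TRUE)
      lam <- stats::runif(need)
      synth <- t(vapply(seq_len(need), function(i) {
        b <- base[i]
        nb <- nn[[b]][sample.int(kk, 1L)]
        Xc[b, ] + lam[i] * (Xc[nb, ] - Xc[b, ])
      }, numeric(ncol(X))))
      colnames(synth) <- colnames(X)
      new_X[[cl]] <- synth
    }
    new_y <- c(new_y, rep(cl, need))
  }
  if (!length(new_X)) return(list(X = X, y = y))
  list(X = rbind(X, do.call(rbind, new_X)), y = c(as.character(y), new_y))
}

.fit_gbt <- function(X, y, w, seed) {
  yf <- factor(y)
  n_class <- nlevels(yf)
  set.seed(seed)
  # feature subsampling spreads gain across correlated biomarkers instead of
  # letting one of a redundant group absorb all importance
  params <- list(max_depth = 6L, eta = 0.3, nthread = 1L, seed = seed,
                 colsample_bytree = 0.5, verbosity = 0L)
  if (n_class == 2L) {
    params$objective <- "binary:logistic"
    label <- as.integer(yf) - 1L
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- n_class
    label <- as.integer(yf) - 1L
  }
  dm <- xgboost::xgb.DMatrix(X, label = label, weight = w)
  fit <- xgboost::xgb.train(params = params, data = dm, nrounds = 100L)
  imp <- xgboost::xgb.importance(model = fit)
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  out[imp$Feature] <- imp$Gain
  out
}

.fit_logistic <- function(X, y, w, seed) {
  yf <- factor(y)
  fam <- if (nlevels(yf) == 2L) "binomial" else "multinomial"
  set.seed(seed)
  fit <- glmnet::glmnet(X, yf, family = fam, weights = w, alpha = 0,
                        lambda = 0.05, standardize = TRUE)
  cf <- glmnet::coef.glmnet(fit)
  if (is.list(cf)) {
    mags <- Reduce(`+`, lapply(cf, function(m) abs(as.numeric(m[-1L, 1L]))))
  } else {
    mags <- abs(as.numeric(cf[-1L, 1L]))
  }
  stats::setNames(mags, colnames(X))
}

.fit_rf <- function(X, y, w, seed) {
  df <- data.frame(..y = factor(y), X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                        num.trees = 300L, importance = "impurity",
                        case.weights = w, seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  out[names(imp)] <- imp
  out
}

#' Per-fold feature importance rankings from the classifier ensemble
#'
#' Trains the three classifier families on the training portion of each of
#' `n_folds` stratified folds. Class imbalance is corrected with
#' inverse-frequency sample weights; when the minority class falls below 30%
#' of the training samples, SMOTE oversampling is additionally applied inside
#' the training fold. Importance measures: gain for boosted trees,
#' coefficient magnitude for the logistic model, impurity decrease for the
#' random forest. Fold `i` uses seed `base_seed + i - 1`.
#'
#' @param cohort An `eb_cohort`.
#' @param cfg An `eb_selection_config`.
#' @return An `eb_rankings` list of `3 * n_folds` named importance vectors,
#'   each with attributes `classifier` and `fold`.
#' @export
train_fold_rankings <- function(cohort, cfg = selection_config()) {
  X <- cohort$X
  y <- factor(cohort$meta$Outcome, levels = cohort$outcome_order)
  if (nlevels(droplevels(y)) < 2L)
    eb_abort("eb_config_error",
             "at least two outcome classes are required for selection")
  tab <- table(y)
  tab <- tab[tab > 0]
  if (any(tab < cfg$n_folds))
    eb_abort("eb_config_error", sprintf(
      "class '%s' has fewer members (%d) than folds (%d); use fewer folds or more data",
      names(tab)[which.min(tab)], min(tab), cfg$n_folds))
  fold <- .stratified_folds(as.character(y), cfg$n_folds, cfg$base_seed)
  fitters <- list(gbt = .fit_gbt, logistic = .fit_logistic,
                  random_forest = .fit_rf)
  rankings <- list()
  for (f in seq_len(cfg$n_folds)) {
    seed_f <- cfg$base_seed + f - 1L
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- as.character(y[tr])
    if (min(table(ytr)) / length(ytr) < 0.30) {
      set.seed(seed_f)
      sm <- .smote(Xtr, ytr)
      Xtr <- sm$X; ytr <- sm$y
    }
    freq <- table(ytr)
    w <- as.numeric(length(ytr) / (length(freq) * freq[ytr]))
    for (nm in names(fitters)) {
      v <- fitters[[nm]](Xtr, ytr, w, seed_f)
      attr(v, "classifier") <- nm
      attr(v, "fold") <- f
      rankings[[paste(nm, f, sep = "_")]] <- v
    }
  }
  structure(rankings, class = "eb_rankings")
}

#' Stability scores from ensemble rankings
#'
#' A feature's appearance count is the number of (classifier, fold) pairs in
#' which it ranks in the top K by importance (ties at the K boundary broken
#' by feature name order); its stability score is the count divided by the
#' number of voting slots (15 for 3 classifiers and 5 folds).
#'
#' @param rankings An `eb_rankings` object.
#' @param K Candidate breadth per list.
#' @return An `eb_stability` data.frame with columns `feature`,
#'   `appearances`, `stability`, `mean_rank` (mean importance rank across
#'   slots, used as a tie-break downstream).
#' @export
stability_scores <- function(rankings, K) {
  feats <- names(rankings[[1L]])
  p <- length(feats)
  if (K > p)
    eb_abort("eb_config_error", sprintf("K (%d) cannot exceed p (%d)", K, p))
  slots <- length(rankings)
  appearances <- stats::setNames(integer(p), feats)
  rank_sum <- stats::setNames(numeric(p), feats)
  for (v in rankings) {
    ord <- order(-v, names(v), method = "radix")
    appearances[ord[seq_len(K)]] <- appearances[ord[seq_len(K)]] + 1L
    rank_sum[ord] <- rank_sum[ord] + seq_len(p)
  }
  structure(data.frame(feature = feats,
                       appearances = unname(appearances),
                       stability = unname(appearances) / slots,
                       mean_rank = unname(rank_sum) / slots,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("eb_stability", "data.frame"), slots = slots)
}

#' Retain features by stability
#'
#' Three retention scenarios based on the set H of features with stability
#' strictly above the 0.5 threshold: "abundant" (|H| >= `N_final`; keep the
#' top `N_final` by stability), "clipped" (1 <= |H| < `N_final`; keep H and
#' clip in next-most-stable features until the count reaches `M_min`, never
#' exceeding `N_final`), "fallback" (H empty; keep the top `M_min` by
#' stability). Ordering is deterministic: descending stability, then mean
#' importance rank, then feature name.
#'
#' @param table An `eb_stability` table.
#' @param N_final Desired final feature count (<= `U_max`).
#' @param M_min Minimum features the downstream model needs
#'   (stages x min cluster size).
#' @param threshold Stability threshold (strict; default 0.5).
#' @return An `eb_selection` list: `selected` (ordered features), `scenario`,
#'   `mean_stability`, `table` (with a `selected` flag column).
#' @export
select_features <- function(table, N_final, M_min, threshold = 0.5) {
  p <- nrow(table)
  if (M_min > p)
    eb_abort("eb_config_error", sprintf(
      "the dataset has %d features but the model constraints require at least %d",
      p, M_min))
  ord <- order_desc_then(table$stability, table$mean_rank, table$feature)
  tab <- table[ord, , drop = FALSE]
  high <- tab$stability > threshold
  n_high <- sum(high)
  if (n_high >= N_final) {
    scenario <- "abundant"
    sel <- tab$feature[seq_len(N_final)]
  } else if (n_high >= 1L) {
    scenario <- "clipped"
    n_keep <- min(max(n_high, M_min), N_final)
    sel <- tab$feature[seq_len(n_keep)]
  } else {
    scenario <- "fallback"
    sel <- tab$feature[seq_len(min(M_min, N_final))]
  }
  table$selected <- table$feature %in% sel
  structure(list(selected = sel, scenario = scenario,
                 mean_stability = mean(tab$stability[tab$feature %in% sel]),
                 table = table),
            class = "eb_selection")
}

#' @method print eb_selection
#' @export
print.eb_selection <- function(x, ...) {
  cat(sprintf("<eb_selection> %d features retained (scenario: %s, mean stability %.3f)\n",
              length(x$selected), x$scenario, x$mean_stability))
  invisible(x)
}

#' Run (or skip) ensemble feature selection
#'
#' Cohorts with fewer than `activation_threshold` features (default 100)
#' bypass selection entirely: every feature is kept with stability 1 and the
#' scenario is `"skipped"`. Otherwise the full ensemble vote runs and the
#' retained set respects the 150-feature hard cap.
#'
#' @inheritParams train_fold_rankings
#' @param M_min Minimum feature count required by the downstream model.
#' @return An `eb_selection`.
#' @export
maybe_skip_selection <- function(cohort, cfg = selection_config(),
                                 M_min = 40L) {
  p <- ncol(cohort$X)
  if (p < cfg$activation_threshold) {
    tab <- structure(data.frame(feature = colnames(cohort$X),
                                appearances = 15L, stability = 1,
                                mean_rank = NA_real_, selected = TRUE,
                                stringsAsFactors = FALSE),
                     class = c("eb_stability", "data.frame"))
    return(structure(list(selected = colnames(cohort$X),
                          scenario = "skipped", mean_stability = 1,
                          table = tab),
                     class = "eb_selection"))
  }
  K <- cfg$top_k %||% determine_k(p, cfg$U_max)
  rankings <- train_fold_rankings(cohort, cfg)
  tab <- stability_scores(rankings, K)
  select_features(tab, N_final = cfg$U_max, M_min = M_min,
                  threshold = cfg$stability_threshold)
}
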