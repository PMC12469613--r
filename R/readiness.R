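# Data readiness: format/schema validation, numeric enforcement, missingness
# filtering with kNN imputation, upper outlier capping, and subject alignment.

.NA_TOKENS <- c("", "na", "nan", "null")

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  delim <- switch(ext, csv = ",", tsv = "\t", psv = "|", NULL)
  if (is.null(delim))
    eb_abort("eb_format_error", sprintf(
      "unsupported file extension '.%s' for '%s'; allowed extensions: .csv, .tsv, .psv",
      ext, basename(path)))
  delim
}

#' Load data and metadata tables
#'
#' Reads the biomarker table and the metadata table, inferring the delimiter
#' from the file extension alone (`.csv` comma, `.tsv` tab, `.psv` pipe,
#' case-insensitive). Both files must have a header row; the data table's
#' first column must be `SubjectID`.
#'
#' @param data_path,meta_path Paths to the data and metadata files.
#' @return A list with data.frames `data` and `meta`.
#' @export
load_tables <- function(data_path, meta_path) {
  for (p in c(data_path, meta_path))
    if (!file.exists(p))
      eb_abort("eb_format_error", sprintf("file not found: '%s'", p))
  read_one <- function(path) {
    delim <- .delim_for(path)
    tab <- tryCatch(
      utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                        comment.char = "", check.names = FALSE,
                        colClasses = "character", fill = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8"),
      error = function(e) eb_abort("eb_coercion_error", sprintf(
        "could not parse '%s' with the '%s' delimiter: %s",
        basename(path), delim, conditionMessage(e))))
    if (ncol(tab) < 1L || nrow(tab) < 1L)
      eb_abort("eb_format_error", sprintf("'%s' is empty", basename(path)))
    tab
  }
  list(data = read_one(data_path), meta = read_one(meta_path))
}

#' Validate the metadata schema
#'
#' Requires columns named exactly `SubjectID` and `Outcome`, and unique
#' subject identifiers. Extra columns are preserved.
#'
#' @param meta Metadata data.frame.
#' @return The validated metadata (invisibly identical content).
#' @export
validate_schema <- function(meta) {
  for (col in c("SubjectID", "Outcome"))
    if (!col %in% names(meta))
      eb_abort("eb_schema_error",
               sprintf("metadata is missing required column '%s'", col),
               column = col)
  dup <- unique(meta$SubjectID[duplicated(meta$SubjectID)])
  if (length(dup))
    eb_abort("eb_schema_error", paste0(
      "duplicate SubjectID values in metadata: ", paste(dup, collapse = ", ")),
      duplicates = dup)
  meta
}

#' Coerce the data table to a numeric matrix
#'
#' Every cell must be numeric or a missing-value token (one of `""`, `"NA"`,
#' `"NaN"`, `"null"`, `"nan"`, case-insensitive, which become `NA`). Any
#' other token is a coercion error reported with its coordinates.
#'
#' @param data Data table with a leading `SubjectID` column.
#' @return Numeric matrix with `SubjectID` rownames.
#' @export
enforce_numeric <- function(data) {
  if (names(data)[1L] != "SubjectID")
    eb_abort("eb_schema_error",
             "first column of the data table must be 'SubjectID'")
  ids <- data$SubjectID
  cells <- as.matrix(data[, -1L, drop = FALSE])
  cells_trim <- trimws(cells)
  is_na_tok <- matrix(tolower(cells_trim) %in% .NA_TOKENS | is.na(cells_trim),
                      nrow(cells), ncol(cells))
  num <- suppressWarnings(array(as.numeric(cells_trim), dim(cells)))
  bad <- which(is.na(num) & !is_na_tok, arr.ind = TRUE)
  if (nrow(bad)) {
    errs <- data.frame(row = bad[, 1L],
                       column = colnames(cells)[bad[, 2L]],
                       token = cells_trim[bad], stringsAsFactors = FALSE)
    show <- utils::head(errs, 5L)
    eb_abort("eb_coercion_error", paste0(
      "non-numeric values in the data table (row, column, token): ",
      paste(sprintf("(%d, %s, '%s')", show$row, show$column, show$token),
            collapse = "; "),
      if (nrow(errs) > 5L) sprintf(" ... and %d more", nrow(errs) - 5L)),
      cells = errs)
  }
  num[is_na_tok] <- NA_real_
  dimnames(num) <- list(ids, colnames(cells))
  num
}

#' Filter high-missingness features and impute the rest
#'
#' Features with a missing fraction above 0.20 are dropped; remaining missing
#' cells are imputed by k-nearest-neighbour imputation (default `k = 5`):
#' neighbour distance is the root-mean-square Euclidean distance over
#' mutually observed features, neighbours must have the target feature
#' observed, ties are broken by lower row index, and the imputed value is the
#' neighbour mean. Falls back to the feature mean when no usable neighbour
#' exists.
#'
#' @param X Numeric matrix with `NA` for missing values.
#' @param k Number of neighbours.
#' @return List with `X` (complete matrix), `dropped` (data.frame of feature
#'   and missing fraction), `imputed_features` (character), `n_imputed`
#'   (imputed cell count).
#' @export
filter_and_impute <- function(X, k = 5L) {
  if (k < 1L) eb_abort("eb_config_error", "k must be at least 1")
  miss_frac <- colMeans(is.na(X))
  drop <- miss_frac > 0.20
  dropped <- data.frame(feature = colnames(X)[drop],
                        missing_fraction = unname(miss_frac[drop]),
                        stringsAsFactors = FALSE)
  X <- X[, !drop, drop = FALSE]
  if (ncol(X) == 0L)
    eb_abort("eb_readiness_error",
             "all features exceeded the 20% missingness threshold")
  miss <- which(is.na(X), arr.ind = TRUE)
  imputed_features <- unique(colnames(X)[miss[, 2L]])
  if (nrow(miss)) {
    X_imp <- X
    for (i in unique(miss[, 1L])) {
      xi <- X[i, ]
      obs_i <- !is.na(xi)
      # squared differences to every other subject over shared features
      diffs <- sweep(X[, obs_i, drop = FALSE], 2L, xi[obs_i])^2
      shared <- rowSums(!is.na(diffs))
      d <- sqrt(rowMeans(diffs, na.rm = TRUE))
      d[i] <- Inf
      d[shared == 0L] <- Inf
      for (j in which(!obs_i)) {
        cand <- which(!is.na(X[, j]) & is.finite(d))
        if (!length(cand)) {
          X_imp[i, j] <- mean(X[, j], na.rm = TRUE)
        } else {
          nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
          X_imp[i, j] <- mean(X[nb, j])
        }
      }
    }
    X <- X_imp
  }
  list(X = X, dropped = dropped, imputed_features = imputed_features,
       n_imputed = nrow(miss))
}

#' Cap upper outliers at Q3 + 1.5 IQR
#'
#' Per feature, values above `Q3 + 1.5 * IQR` are capped at that bound.
#' Quartiles use linear interpolation between order statistics (R's default
#' type-7 convention). Capping is one-sided: low values are untouched.
#'
#' @param X Complete numeric matrix.
#' @return List with `X` (capped), `rules` (data.frame feature/q3/iqr/cap),
#'   and `n_capped` (number of modified cells).
#' @export
cap_outliers <- function(X) {
  q3 <- apply(X, 2L, stats::quantile, probs = 0.75, names = FALSE, type = 7)
  q1 <- apply(X, 2L, stats::quantile, probs = 0.25, names = FALSE, type = 7)
  iqr <- q3 - q1
  cap <- q3 + 1.5 * iqr
  over <- sweep(X, 2L, cap, `>`)
  n_capped <- sum(over)
  X_cap <- pmin(X, matrix(cap, nrow(X), ncol(X), byrow = TRUE))
  list(X = X_cap,
       rules = data.frame(feature = colnames(X), q3 = q3, iqr = iqr,
                          cap = cap, stringsAsFactors = FALSE),
       n_capped = n_capped)
}

#' Align the data matrix with the metadata
#'
#' Matches subjects by exact `SubjectID`. Subjects present in only one table
#' are dropped with a warning listing them; the surviving subject order
#' follows the metadata order.
#'
#' @param X Numeric matrix with `SubjectID` rownames.
#' @param meta Validated metadata.
#' @param outcome_order Optional explicit ordering of outcome labels.
#' @param baseline Optional baseline class label (defaults to the first
#'   element of `outcome_order` when given).
#' @return An `eb_cohort` object.
#' @export
align_cohort <- function(X, meta, outcome_order = NULL, baseline = NULL) {
  common <- intersect(meta$SubjectID, rownames(X))
  if (!length(common))
    eb_abort("eb_readiness_error",
             "no overlapping SubjectID values between data and metadata")
  only <- c(setdiff(meta$SubjectID, rownames(X)),
            setdiff(rownames(X), meta$SubjectID))
  if (length(only))
    eb_warning("eb_alignment_warning", paste0(
      "dropping subjects present in only one table: ",
      paste(only, collapse = ", ")), dropped = only)
  meta <- meta[meta$SubjectID %in% common, , drop = FALSE]
  X <- X[meta$SubjectID, , drop = FALSE]
  new_cohort(X, meta, outcome_order = outcome_order, baseline = baseline)
}

#' Construct a cohort object
#'
#' @param X Numeric matrix, subjects by features, `SubjectID` rownames.
#' @param meta Metadata aligned 1:1 with rows of `X`.
#' @param outcome_order Optional ordered outcome labels (needed for ordinal
#'   metrics with three or more classes).
#' @param baseline Baseline (least-affected) class, used to fit pre-event
#'   distributions; `NULL` means no designated baseline.
#' @return An `eb_cohort` list with elements `X`, `meta`, `outcome_order`,
#'   `baseline`.
#' @export
new_cohort <- function(X, meta, outcome_order = NULL, baseline = NULL) {
  stopifnot(nrow(X) == nrow(meta), identical(rownames(X), meta$SubjectID))
  if (length(baseline) && is.na(baseline)) baseline <- NULL
  lev <- outcome_order %||% unique(meta$Outcome)
  if (!all(meta$Outcome %in% lev))
    eb_abort("eb_schema_error", "outcome_order does not cover all outcomes")
  if (!is.null(baseline) && !baseline %in% lev)
    eb_abort("eb_schema_error", "baseline is not an outcome label")
  structure(list(X = X, meta = meta,
                 outcome_order = lev, baseline = baseline,
                 explicit_order = !is.null(outcome_order)),
            class = "eb_cohort")
}

#' @method print eb_cohort
#' @export
print.eb_cohort <- function(x, ...) {
  cat(sprintf("<eb_cohort> %d subjects x %d features\n",
              nrow(x$X), ncol(x$X)))
  cat("  outcomes:", paste(sprintf(
    "%s (%d)", x$outcome_order,
    tabulate(factor(x$meta$Outcome, x$outcome_order))), collapse = ", "), "\n")
  if (!is.null(x$baseline)) cat("  baseline class:", x$baseline, "\n")
  invisible(x)
}

#' Run the full data-readiness stage
#'
#' Loads, validates, coerces, filters/imputes, caps, and aligns the input
#' pair, producing a modelling-ready cohort plus a readiness report.
#'
#' @inheritParams load_tables
#' @inheritParams filter_and_impute
#' @inheritParams align_cohort
#' @return List with `cohort` (an `eb_cohort`) and `report` (an
#'   `eb_readiness_report`: dropped features, imputed features, capped-cell
#'   count, capping rules).
#' @export
run_readiness <- function(data_path, meta_path, k = 5L,
                          outcome_order = NULL, baseline = NULL) {
  tabs <- load_tables(data_path, meta_path)
  meta <- validate_schema(tabs$meta)
  X <- enforce_numeric(tabs$data)
  fi <- filter_and_impute(X, k = k)
  co <- cap_outliers(fi$X)
  cohort <- align_cohort(co$X, meta, outcome_order = outcome_order,
                         baseline = baseline)
  report <- structure(list(
    dropped_features_missingness = fi$dropped,
    imputed_features = fi$imputed_features,
    n_imputed_cells = fi$n_imputed,
    capped_cells = co$n_capped,
    capping_rules = co$rules
  ), class = "eb_readiness_report")
  list(cohort = cohort, report = report)
}

#' @method print eb_readiness_report
#' @export
print.eb_readiness_report <- function(x, ...) {
  cat("<eb_readiness_report>\n")
  cat(sprintf("  features dropped for missingness > 20%%: %d\n",
              nrow(x$dropped_features_missingness)))
  cat(sprintf("  features imputed (kNN): %d; imputed cells: %d\n",
              length(x$imputed_features), x$n_imputed_cells))
  cat(sprintf("  cells capped at Q3 + 1.5*IQR: %d\n", x$capped_cells))
  invisible(x)
}
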