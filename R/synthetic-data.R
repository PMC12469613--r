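#' Specify a synthetic biomarker cohort
#'
#' Builds a validated specification for the synthetic-cohort generator.
#' Cohorts follow a clustered event-progression model: each subject carries a
#' latent subtype and a latent stage in `0..n_stages`; every informative
#' biomarker belongs to one stage-cluster of its subtype's planted ordering
#' and shifts its mean by `effect_size` (in units of the pre-event standard
#' deviation, `noise_sd`) once the subject's stage reaches that cluster.
#' Non-informative biomarkers are pure noise. Missing cells are masked
#' completely at random.
#'
#' @param n_subjects Number of subjects.
#' @param n_features Total number of biomarkers (columns).
#' @param n_informative Number of biomarkers carrying planted signal; must be
#'   at least `2 * n_stages`.
#' @param n_subtypes Number of planted subtypes, each with its own random
#'   ordering of the informative biomarkers.
#' @param n_stages Number of post-baseline stages (stage support is
#'   `0..n_stages`).
#' @param effect_size Post-event mean shift, in pre-event SD units.
#' @param noise_sd Standard deviation of measurement noise.
#' @param missing_rate Probability that any one cell is masked as missing.
#' @param outcome_scheme One of `"binary_case_control"`,
#'   `"ordered_three_class"`, `"three_class_with_control"`. Outcome labels are
#'   derived from contiguous stage bands (see Details).
#' @param outcome_props Optional class proportions (summing to 1); defaults to
#'   equal classes.
#' @param subtype_props Optional subtype proportions (summing to 1).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#'
#' @details Stage bands per scheme: `binary_case_control` splits stage support
#'   at `floor(n_stages / 2)` (early band = first class, e.g. "Normal");
#'   `ordered_three_class` cuts `0..n_stages` into three contiguous,
#'   near-equal bands ("Localized" < "Invasive" < "Metastatic");
#'   `three_class_with_control` reserves stage 0 for "Control" and splits
#'   `1..n_stages` into two bands ("AsymAD", "AD"). Subjects are assigned an
#'   outcome per `outcome_props`, then a stage uniformly within its band, so
#'   outcomes and stage bands are mutually consistent.
#'
#' @return An object of class `eb_generator_spec`.
#' @seealso [generate_cohort()], [cohort_preset()]
#' @export
generator_spec <- function(n_subjects,
                           n_features,
                           n_informative = n_features,
                           n_subtypes = 1L,
                           n_stages = 4L,
                           effect_size = 5,
                           noise_sd = 1,
                           missing_rate = 0,
                           outcome_scheme = c("binary_case_control",
                                              "ordered_three_class",
                                              "three_class_with_control"),
                           outcome_props = NULL,
                           subtype_props = NULL,
                           seed = 42L) {
  outcome_scheme <- match.arg(outcome_scheme)
  if (n_informative > n_features)
    eb_abort("eb_config_error", "n_informative cannot exceed n_features")
  if (n_informative < 2L * n_stages)
    eb_abort("eb_config_error", sprintf(
      "infeasible spec: n_informative (%d) must be at least 2 * n_stages (%d)",
      n_informative, 2L * n_stages))
  if (effect_size < 0)
    eb_abort("eb_config_error", "effect_size must be non-negative")
  n_classes <- if (outcome_scheme == "binary_case_control") 2L else 3L
  if (is.null(outcome_props)) outcome_props <- rep(1 / n_classes, n_classes)
  if (length(outcome_props) != n_classes || abs(sum(outcome_props) - 1) > 1e-8)
    eb_abort("eb_config_error", "outcome_props must sum to 1 with one entry per class")
  if (is.null(subtype_props)) subtype_props <- rep(1 / n_subtypes, n_subtypes)
  if (length(subtype_props) != n_subtypes || abs(sum(subtype_props) - 1) > 1e-8)
    eb_abort("eb_config_error", "subtype_props must sum to 1 with one entry per subtype")
  structure(list(
    n_subjects = as.integer(n_subjects), n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    n_subtypes = as.integer(n_subtypes), n_stages = as.integer(n_stages),
    effect_size = effect_size, noise_sd = noise_sd,
    missing_rate = missing_rate, outcome_scheme = outcome_scheme,
    outcome_props = outcome_props, subtype_props = subtype_props,
    seed = as.integer(seed)
  ), class = "eb_generator_spec")
}

#' Preset cohort shapes
#'
#' Named generator specifications emulating the shapes of three published
#' cohort types: a binary tumour/normal bulk transcriptomics cohort
#' (`"coad_like"`: 446 subjects, 5092 features, 39 vs 407), a three-ordered-
#' outcome transcriptomics cohort with no healthy controls (`"blca_like"`:
#' 343 subjects, 5727 features, 19/207/117), and a compact three-outcome,
#' three-subtype CSF proteomics panel (`"ehbs_like"`: 392 subjects, 71
#' features, 133/130/129).
#'
#' @param name One of `"coad_like"`, `"blca_like"`, `"ehbs_like"`.
#' @param seed Integer seed passed through to the spec.
#' @return An `eb_generator_spec`.
#' @export
cohort_preset <- function(name, seed = 42L) {
  presets <- c("coad_like", "blca_like", "ehbs_like")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    eb_abort("eb_config_error", paste0(
      "unknown preset; available presets: ", paste(presets, collapse = ", ")))
  switch(name,
    coad_like = generator_spec(
      n_subjects = 446L, n_features = 5092L, n_informative = 60L,
      n_subtypes = 1L, n_stages = 4L,
      outcome_scheme = "binary_case_control",
      outcome_props = c(39, 407) / 446, seed = seed),
    blca_like = generator_spec(
      n_subjects = 343L, n_features = 5727L, n_informative = 68L,
      n_subtypes = 1L, n_stages = 5L,
      outcome_scheme = "ordered_three_class",
      outcome_props = c(19, 207, 117) / 343, seed = seed),
    ehbs_like = generator_spec(
      n_subjects = 392L, n_features = 71L, n_informative = 71L,
      n_subtypes = 3L, n_stages = 4L,
      outcome_scheme = "three_class_with_control",
      outcome_props = c(133, 130, 129) / 392, seed = seed)
  )
}

.outcome_labels <- function(scheme) {
  switch(scheme,
    binary_case_control = c("Normal", "Tumor"),
    ordered_three_class = c("Localized", "Invasive", "Metastatic"),
    three_class_with_control = c("Control", "AsymAD", "AD"))
}

# Contiguous stage bands (over support 0..S) backing each outcome class.
.stage_bands <- function(scheme, S) {
  support <- 0:S
  switch(scheme,
    binary_case_control = {
      cut_at <- floor(S / 2)
      list(support[support <= cut_at], support[support > cut_at])
    },
    ordered_three_class = {
      idx <- cut(support, breaks = 3, labels = FALSE)
      split(support, idx)
    },
    three_class_with_control = {
      rest <- 1:S
      half <- ceiling(S / 2)
      list(0L, rest[rest <= half], rest[rest > half])
    })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from an [generator_spec()] and optionally writes it to disk
#' as a `data.csv` / `meta.csv` pair matching the readiness schema (first
#' column `SubjectID`, metadata columns `SubjectID`, `Outcome`).
#'
#' @param spec An `eb_generator_spec`.
#' @param dir Optional output directory; created if needed.
#' @return A list with elements `data` (data.frame, `SubjectID` + features),
#'   `meta` (data.frame with `SubjectID`, `Outcome`), `truth` (per-subject
#'   true subtype/stage, per-feature informative flag, and the planted
#'   stage-cluster assignment per subtype), `outcome_order`, `baseline`
#'   (baseline class name or `NA`), and `paths` when `dir` is given.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "eb_generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects; p <- spec$n_features; S <- spec$n_stages
  K <- spec$n_subtypes
  labels <- .outcome_labels(spec$outcome_scheme)
  bands <- .stage_bands(spec$outcome_scheme, S)

  # Outcome counts honour the requested proportions exactly (up to rounding).
  counts <- floor(spec$outcome_props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    top_up <- order(-(spec$outcome_props * n - counts))[seq_len(rem)]
    counts[top_up] <- counts[top_up] + 1L
  }
  outcome_idx <- sample(rep.int(seq_along(labels), counts))
  stage <- vapply(outcome_idx, function(ci) {
    band <- bands[[ci]]
    if (length(band) == 1L) band else sample(band, 1L)
  }, integer(1))

  subtype <- sample(seq_len(K), n, replace = TRUE, prob = spec$subtype_props)

  feat_names <- sprintf("F%04d", seq_len(p))
  # informative columns are a random subset so that name-based tie-breaks
  # downstream cannot systematically favour (or disfavour) planted signal
  informative <- sort(sample.int(p, spec$n_informative))
  # Planted ordering per subtype: permutation of informative features cut
  # into S near-equal contiguous clusters.
  sizes <- rep(spec$n_informative %/% S, S)
  extra <- spec$n_informative %% S
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cluster_of <- function(perm) {
    cl <- integer(p)
    cl[perm] <- rep.int(seq_len(S), sizes)
    cl
  }
  partitions <- lapply(seq_len(K), function(k) cluster_of(sample(informative)))

  X <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p,
              dimnames = list(NULL, feat_names))
  delta <- spec$effect_size * spec$noise_sd
  for (k in seq_len(K)) {
    rows <- which(subtype == k)
    if (!length(rows)) next
    cl <- partitions[[k]]
    # event m has occurred for subject i iff cluster(m) <= stage(i)
    shift <- outer(stage[rows], cl[informative], ">=") * delta
    X[rows, informative] <- X[rows, informative] + shift
  }

  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
    X[mask] <- NA_real_
  }

  ids <- sprintf("S%04d", seq_len(n))
  data <- data.frame(SubjectID = ids, X, check.names = FALSE,
                     stringsAsFactors = FALSE)
  meta <- data.frame(SubjectID = ids, Outcome = labels[outcome_idx],
                     stringsAsFactors = FALSE)
  baseline <- if (spec$outcome_scheme == "ordered_three_class") NA_character_
              else labels[1L]
  truth <- list(
    subtype = subtype, stage = stage,
    informative = feat_names[informative],
    partitions = lapply(partitions, function(cl) {
      stats::setNames(cl[informative], feat_names[informative])
    })
  )
  out <- list(data = data, meta = meta, truth = truth,
              outcome_order = labels, baseline = baseline)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(data = file.path(dir, "data.csv"),
                  meta = file.path(dir, "meta.csv"))
    utils::write.csv(data, paths$data, row.names = FALSE)
    utils::write.csv(meta, paths$meta, row.names = FALSE)
    out$paths <- paths
  }
  out
}
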