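# Artifact export: subject/biomarker annotation CSVs and the three figure
# families (stage-by-outcome bars, biomarker heatmaps, positional-confidence
# matrices). Every figure gets a companion CSV so downstream checks never
# parse pixels; figure size and dpi are fixed for reproducibility.

.save_png <- function(plot, path, width = 8, height = 6) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 150, type = "cairo")
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Export subject- and biomarker-level annotations
#'
#' Writes `subject_assignments.csv` (SubjectID, Outcome, Subtype, Stage,
#' PosteriorProb) and `biomarker_stages.csv` (Biomarker, Subtype, ModalStage,
#' Confidence), where ModalStage is the most frequent MCMC stage of the
#' biomarker (ties toward the earlier stage) and Confidence is the maximum of
#' its positional-confidence row.
#'
#' @param assignments MAP assignment table.
#' @param confidence An `eb_confidence` from [run_mcmc()].
#' @param out_dir Output directory.
#' @return Named list of file paths.
#' @export
export_annotations <- function(assignments, confidence, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subj_path <- file.path(out_dir, "subject_assignments.csv")
  utils::write.csv(assignments, subj_path, row.names = FALSE)
  rows <- list()
  for (k in seq_along(confidence$P)) {
    P <- confidence$P[[k]]
    modal <- apply(P, 1L, which.max)  # which.max takes the earliest tie
    rows[[k]] <- data.frame(
      Biomarker = rownames(P), Subtype = k, ModalStage = as.integer(modal),
      Confidence = P[cbind(seq_len(nrow(P)), modal)],
      stringsAsFactors = FALSE)
  }
  bio <- do.call(rbind, rows)
  bio_path <- file.path(out_dir, "biomarker_stages.csv")
  utils::write.csv(bio, bio_path, row.names = FALSE)
  list(subject_assignments = subj_path, biomarker_stages = bio_path)
}

#' Stage-distribution bar plots
#'
#' One panel per subtype: grouped bars of subject counts per retained stage,
#' one bar per outcome. Stages removed by [filter_sparse_stages()] are
#' absent. A companion CSV holds the plotted counts.
#'
#' @param assignments MAP assignment table.
#' @param stages Retained stage set (default: all observed stages).
#' @param out_dir Output directory.
#' @return Path of the PNG (the CSV sits next to it).
#' @export
plot_stage_distribution <- function(assignments,
                                    stages = sort(unique(assignments$Stage)),
                                    out_dir = ".") {
  keep <- assignments[assignments$Stage %in% stages, , drop = FALSE]
  counts <- as.data.frame(table(Subtype = keep$Subtype, Stage = keep$Stage,
                                Outcome = keep$Outcome),
                          stringsAsFactors = FALSE)
  names(counts)[4L] <- "Count"
  counts <- counts[order(counts$Subtype, counts$Stage, counts$Outcome), ]
  csv_path <- file.path(out_dir, "stage_distribution.csv")
  utils::write.csv(counts, csv_path, row.names = FALSE)
  p <- ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$Stage, y = .data$Count, fill = .data$Outcome)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::facet_wrap(~Subtype, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Inferred stage", y = "Subjects") +
    ggplot2::theme_minimal()
  .save_png(p, file.path(out_dir, "stage_distribution.png"))
}

#' Biomarker heatmap by stage and outcome
#'
#' Mean expression of each model biomarker in every (stage, outcome) cell,
#' clipped at the capping rule, then min-max rescaled per biomarker to
#' `[0, 1]`; rows are ordered by mean expression in the baseline class (or
#' the first outcome). Diverging palette: high = red, low = blue.
#'
#' @param cohort The model cohort (selected features).
#' @param assignments MAP assignment table aligned with the cohort.
#' @param out_dir Output directory.
#' @return Path of the PNG.
#' @export
plot_heatmap <- function(cohort, assignments, out_dir = ".") {
  X <- cap_outliers(cohort$X)$X
  rng <- apply(X, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], .Machine$double.eps)
  X01 <- sweep(sweep(X, 2L, rng[1L, ]), 2L, span, `/`)
  cellkey <- interaction(assignments$Stage, assignments$Outcome, drop = TRUE,
                         sep = " / ")
  means <- apply(X01, 2L, function(col) tapply(col, cellkey, mean))
  base_cls <- cohort$baseline %||% cohort$outcome_order[1L]
  # row order uses raw (unscaled) mean expression in the baseline class
  base_mean <- colMeans(cohort$X[assignments$Outcome == base_cls, ,
                                 drop = FALSE])
  if (!any(assignments$Outcome == base_cls)) base_mean <- colMeans(cohort$X)
  feat_order <- colnames(X)[order(base_mean, colnames(X))]
  df <- expand.grid(cell = rownames(means), Biomarker = colnames(means),
                    stringsAsFactors = FALSE)
  df$Mean <- as.vector(means)
  df$Biomarker <- factor(df$Biomarker, levels = feat_order)
  df$cell <- factor(df$cell, levels = rownames(means))
  utils::write.csv(
    df[order(df$Biomarker, df$cell), c("Biomarker", "cell", "Mean")],
    file.path(out_dir, "biomarker_heatmap.csv"), row.names = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cell, y = .data$Biomarker, fill = .data$Mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0.5, limits = c(0, 1)) +
    ggplot2::labs(x = "Stage / Outcome", y = NULL, fill = "Scaled mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_text(size = 4))
  .save_png(p, file.path(out_dir, "biomarker_heatmap.png"), height = 8)
}

#' Positional-confidence matrices
#'
#' One panel per subtype: biomarkers (rows, sorted by modal stage then by
#' confidence) by stages (columns), with red intensity equal to the MCMC
#' frequency of the biomarker occupying the stage. Informative data produce
#' the diagonal "staircase" band.
#'
#' @param confidence An `eb_confidence`.
#' @param out_dir Output directory.
#' @return Path of the PNG.
#' @export
plot_positional_confidence <- function(confidence, out_dir = ".") {
  long <- list()
  for (k in seq_along(confidence$P)) {
    P <- confidence$P[[k]]
    modal <- apply(P, 1L, which.max)
    conf <- P[cbind(seq_len(nrow(P)), modal)]
    ord <- order(modal, -conf, rownames(P))
    long[[k]] <- data.frame(
      Subtype = k,
      Biomarker = factor(rownames(P), levels = rev(rownames(P)[ord])),
      Stage = rep(seq_len(ncol(P)), each = nrow(P)),
      Frequency = as.vector(P), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, long)
  utils::write.csv(
    df[order(df$Subtype, df$Biomarker, df$Stage), ],
    file.path(out_dir, "positional_confidence.csv"), row.names = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$Stage, y = .data$Biomarker, fill = .data$Frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~Subtype, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Stage", y = NULL, fill = "Frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
  .save_png(p, file.path(out_dir, "positional_confidence.png"), height = 8)
}
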