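# High-level orchestration: train the classifier on the training ROIs,
# run internal validation on the training nodules, and derive the data-driven
# pixel-fraction cutoffs (Youden single cutoff and the double cutoff that
# bounds the gray zone).

#' Train the classifier and derive cutoffs on the training set
#'
#' Preprocesses the training samples, learns the shared feature bins from
#' the training ROI-average peaks, fits the L1 multinomial classifier on the
#' ROI matrix, runs the three per-nodule decision rules on the training
#' nodules (internal validation), and derives the Youden cutoff and the
#' double cutoff from the training malignant-pixel fractions.
#'
#' @param cohort An `msi_cohort`.
#' @param cfg An [preprocess_config()].
#' @param cv_folds Cross-validation folds for the penalty selection.
#' @param rng_seed Seed for the fold assignment.
#' @param thresholds Thresholds used for the internal-validation calls.
#' @return An `msi_fit`: `model`, `internal_diagnosis`, `youden_cutoff`,
#'   `double_cutoff`, `derived_thresholds`, `roi_labels`, `n_excluded_pixels`.
#' @export
msi_train <- function(cohort, cfg = preprocess_config(), cv_folds = 5,
                      rng_seed = 1L, thresholds = diagnosis_thresholds()) {
  train_ids <- cohort$manifest$sample_id[cohort$manifest$set == "training"]
  if (!length(train_ids)) abort("cohort has no training samples")
  pd <- extract_peaks(cohort, cfg, train_ids)
  roi_pk <- roi_peak_tibble(pd)
  if (is.null(roi_pk) || !nrow(roi_pk)) abort("no training ROI peaks")
  bins <- bin_peaks(roi_pk, cfg$bin_tolerance, "roi")$feature_mzs
  mats <- unit_matrices(pd, bins, cfg)
  model <- fit_lasso_multinomial(mats$roi, mats$roi$meta$label,
                                 cv_folds = cv_folds, rng_seed = rng_seed)

  internal <- diagnose_peakdata(pd, model, cfg, thresholds)
  truth <- cohort$manifest$truth[match(internal$sample_id,
                                       cohort$manifest$sample_id)]
  ok <- !is.na(internal$malignant_pixel_fraction)
  youden <- derive_youden_cutoff(internal$malignant_pixel_fraction[ok],
                                 truth[ok])
  dbl <- derive_double_cutoff(internal$malignant_pixel_fraction[ok],
                              truth[ok])
  derived <- diagnosis_thresholds(
    pixel_cutoff_low = min(dbl[["low"]], as.numeric(youden)),
    pixel_cutoff_high = as.numeric(youden),
    roi_cutoff = thresholds$roi_cutoff
  )
  structure(list(model = model, internal_diagnosis = internal,
                 internal_truth = truth,
                 youden_cutoff = youden, double_cutoff = dbl,
                 derived_thresholds = derived,
                 thresholds = thresholds,
                 n_excluded_pixels = mats$n_excluded_pixels,
                 cfg = cfg),
            class = "msi_fit")
}

#' @export
print.msi_fit <- function(x, ...) {
  cat("<msi_fit>\n")
  print(x$model)
  cat("  Youden pixel cutoff: ", pct_round(100 * as.numeric(x$youden_cutoff)),
      "%  double cutoff: [", pct_round(100 * x$double_cutoff[["low"]]), "%, ",
      pct_round(100 * x$double_cutoff[["high"]]), "%]\n", sep = "")
  invisible(x)
}

#' One-row training summary
#' @param x An `msi_fit` object.
#' @param ... Unused.
#' @export
glance.msi_fit <- function(x, ...) {
  g <- glance(x$model)
  g$youden_cutoff <- as.numeric(x$youden_cutoff)
  g$double_cutoff_low <- x$double_cutoff[["low"]]
  g$double_cutoff_high <- x$double_cutoff[["high"]]
  g
}
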