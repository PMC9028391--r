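# Per-nodule diagnosis. Three aggregation strategies turn unit-level class
# calls into a benign/malignant call per nodule: (1) the class of the overall
# average spectrum; (2) malignant iff at least one third of the ROIs is
# called PTC; (3) malignant iff the fraction of PTC pixels exceeds a cutoff
# estimated by the Youden index on the training set. A three-level triage
# adds a gray zone between a lower and an upper pixel-fraction cutoff.

#' Diagnosis thresholds
#'
#' Defaults: the pixel rule calls a nodule malignant when strictly more than
#' 16.7% of its classified pixels are PTC; the three-level triage labels
#' nodules with less than 7.0% benign, 7.0-16.7% gray zone, and more than
#' 16.7% malignant; the ROI rule requires at least one third of ROIs.
#'
#' @param pixel_cutoff_low Lower (benign) pixel-fraction cutoff.
#' @param pixel_cutoff_high Upper (malignant) pixel-fraction cutoff.
#' @param roi_cutoff Minimal fraction of malignant ROIs.
#' @return An `msi_thresholds` list.
#' @export
diagnosis_thresholds <- function(pixel_cutoff_low = 0.070,
                                 pixel_cutoff_high = 0.167,
                                 roi_cutoff = 1 / 3) {
  if (!(pixel_cutoff_low >= 0 && pixel_cutoff_low <= pixel_cutoff_high &&
        pixel_cutoff_high <= 1)) {
    abort("need 0 <= low <= high <= 1")
  }
  if (!(roi_cutoff > 0 && roi_cutoff <= 1)) abort("`roi_cutoff` must be in (0, 1]")
  structure(list(pixel_cutoff_low = pixel_cutoff_low,
                 pixel_cutoff_high = pixel_cutoff_high,
                 roi_cutoff = roi_cutoff),
            class = "msi_thresholds")
}

#' Overall-average-spectrum diagnosis
#'
#' The nodule call is the binary mapping of the highest of the three class
#' probabilities on the overall average spectrum (HP/HT benign, PTC
#' malignant).
#'
#' @param p_hp,p_ht,p_ptc Class probabilities of the overall average
#'   spectrum (vectorized over nodules).
#' @return Character vector `benign`/`malignant`.
#' @export
diagnose_overall_average <- function(p_hp, p_ht, p_ptc) {
  binary_call(call_from_probs(p_hp, p_ht, p_ptc))
}

#' ROI-based diagnosis
#'
#' Malignant iff the fraction of ROIs called PTC reaches `roi_cutoff`
#' (inclusive: "at least one third").
#'
#' @param roi_calls Character vector of per-ROI class calls for one nodule.
#' @param roi_cutoff Fraction threshold (default 1/3).
#' @return List with `fraction` (malignant ROI fraction) and `call`.
#' @export
diagnose_by_rois <- function(roi_calls, roi_cutoff = 1 / 3) {
  if (!length(roi_calls)) {
    return(list(fraction = NA_real_, call = "inadequate"))
  }
  fr <- mean(roi_calls == "PTC")
  list(fraction = fr, call = ifelse(fr >= roi_cutoff, "malignant", "benign"))
}

#' Pixel-by-pixel diagnosis
#'
#' The malignant pixel fraction is the share of retained (classified) pixels
#' called PTC; the nodule is malignant iff that fraction is strictly above
#' the cutoff.
#'
#' @param pixel_calls Character vector of per-pixel class calls for one
#'   nodule (retained pixels only).
#' @param pixel_cutoff_high Fraction cutoff (default 0.167).
#' @return List with `fraction`, `n_pixels` and `call`.
#' @export
diagnose_pixelwise <- function(pixel_calls, pixel_cutoff_high = 0.167) {
  if (!length(pixel_calls)) {
    return(list(fraction = NA_real_, n_pixels = 0L, call = "inadequate"))
  }
  fr <- mean(pixel_calls == "PTC")
  list(fraction = fr, n_pixels = length(pixel_calls),
       call = ifelse(fr > pixel_cutoff_high, "malignant", "benign"))
}

#' Three-level gray-zone triage
#'
#' Benign below the low cutoff (strict), malignant above the high cutoff
#' (strict), gray zone in the closed band between them.
#'
#' @param fraction Malignant pixel fraction(s) in `[0, 1]`.
#' @param low,high Band cutoffs, `low <= high`.
#' @return Character vector `benign`/`gray`/`malignant`.
#' @export
diagnose_three_level <- function(fraction, low = 0.070, high = 0.167) {
  if (low > high) abort("`low` must be <= `high`")
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    abort("fractions must be in [0, 1]")
  }
  out <- ifelse(fraction < low, "benign",
                ifelse(fraction > high, "malignant", "gray"))
  out
}

# candidate cutoffs: midpoints between consecutive distinct sorted values
# plus one sentinel below the minimum and one above the maximum, so the
# strict-> decision rule is unambiguous at every candidate
cutoff_candidates <- function(values) {
  v <- sort(unique(values))
  d <- if (length(v) > 1) min(diff(v)) / 2 else 1e-3
  c(v[1] - d, if (length(v) > 1) v[-length(v)] + diff(v) / 2, v[length(v)] + d)
}

#' Youden-index cutoff on training malignant-pixel fractions
#'
#' Scans candidate cutoffs (midpoints between consecutive distinct observed
#' fractions plus sentinels) and returns the cutoff maximizing
#' J = sensitivity + specificity - 1 under the rule "malignant iff fraction
#' strictly above the cutoff". Ties return the smallest such cutoff.
#'
#' @param fraction Malignant pixel fraction per training nodule.
#' @param truth Truth label per nodule (`benign`/`malignant`).
#' @return The selected cutoff, with attributes `j`, `sensitivity`,
#'   `specificity`.
#' @export
derive_youden_cutoff <- function(fraction, truth) {
  check_two_classes(truth)
  cand <- cutoff_candidates(fraction)
  mal <- fraction[truth == "malignant"]
  ben <- fraction[truth == "benign"]
  sens <- vapply(cand, function(c) mean(mal > c), 0)
  spec <- vapply(cand, function(c) mean(ben <= c), 0)
  j <- sens + spec - 1
  i <- which(j >= max(j) - 1e-12)[1]
  structure(cand[i], j = j[i], sensitivity = sens[i], specificity = spec[i])
}

#' Double cutoff for the three-level triage
#'
#' Estimated on the training set so that the malignant call (fraction
#' strictly above `high`) has maximal specificity, with `high` the smallest
#' such candidate, and the benign call (fraction strictly below `low`) has
#' maximal sensitivity, with `low` the largest candidate not exceeding
#' `high`. The gray zone is the closed band `[low, high]`; `low == high`
#' (empty gray zone) is allowed on well-separated data.
#'
#' @inheritParams derive_youden_cutoff
#' @return Named numeric vector `c(low = , high = )`.
#' @export
derive_double_cutoff <- function(fraction, truth) {
  check_two_classes(truth)
  cand <- cutoff_candidates(fraction)
  mal <- fraction[truth == "malignant"]
  ben <- fraction[truth == "benign"]
  spec_high <- vapply(cand, function(c) mean(ben <= c), 0)
  high <- min(cand[spec_high >= max(spec_high) - 1e-12])
  low_cand <- cand[cand <= high + 1e-12]
  sens_low <- vapply(low_cand, function(c) mean(mal >= c), 0)
  low <- max(low_cand[sens_low >= max(sens_low) - 1e-12])
  c(low = low, high = high)
}

check_two_classes <- function(truth) {
  bad <- setdiff(unique(truth), c("benign", "malignant"))
  if (length(bad)) abort(paste0("unknown truth label: ", paste(bad, collapse = ", ")))
  if (!all(c("benign", "malignant") %in% truth)) {
    abort("both truth classes must be present")
  }
}

#' Run the full per-nodule diagnosis over a cohort
#'
#' Preprocesses the requested samples, classifies pixels, ROI-average and
#' overall-average spectra with the fitted model, and applies the three
#' aggregation rules plus the three-level triage.
#'
#' @param cohort An `msi_cohort`.
#' @param model An `msi_lasso` model (its feature axis defines the bins).
#' @param cfg An [preprocess_config()].
#' @param thresholds An [diagnosis_thresholds()].
#' @param sample_ids Samples to diagnose (default: all validation samples if
#'   any, otherwise all).
#' @return An `msi_diagnosis` tibble: one row per nodule with
#'   `malignant_pixel_fraction`, `n_pixels_classified`,
#'   `roi_malignant_fraction`, `call_overall_avg`, `call_roi`, `call_pixel`,
#'   `call_three_level`.
#' @export
msi_diagnose <- function(cohort, model, cfg = preprocess_config(),
                         thresholds = diagnosis_thresholds(),
                         sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- cohort$manifest$sample_id
    if (any(cohort$manifest$set == "validation")) {
      sample_ids <- cohort$manifest$sample_id[cohort$manifest$set == "validation"]
    }
  }
  pd <- extract_peaks(cohort, cfg, sample_ids)
  diagnose_peakdata(pd, model, cfg, thresholds)
}

# shared by msi_diagnose and the internal-validation path: peak data in,
# per-nodule diagnosis tibble out
diagnose_peakdata <- function(pd, model, cfg, thresholds) {
  mats <- unit_matrices(pd, model$feature_mzs, cfg)
  pixel_calls <- classify_units(model, mats$pixel)
  roi_calls <- classify_units(model, mats$roi)
  overall <- classify_units(model, mats$overall)

  rows <- lapply(names(pd), function(sid) {
    pc <- pixel_calls$class_call[pixel_calls$sample_id == sid]
    rc <- roi_calls$class_call[roi_calls$sample_id == sid]
    ov <- overall[overall$sample_id == sid, ]
    px <- diagnose_pixelwise(pc, thresholds$pixel_cutoff_high)
    ro <- diagnose_by_rois(rc, thresholds$roi_cutoff)
    tibble::tibble(
      sample_id = sid,
      n_pixels_classified = px$n_pixels,
      malignant_pixel_fraction = px$fraction,
      roi_malignant_fraction = ro$fraction,
      call_overall_avg = if (nrow(ov)) {
        diagnose_overall_average(ov$p_hp, ov$p_ht, ov$p_ptc)
      } else "inadequate",
      call_roi = ro$call,
      call_pixel = px$call,
      call_three_level = if (is.na(px$fraction)) "inadequate" else {
        diagnose_three_level(px$fraction, thresholds$pixel_cutoff_low,
                             thresholds$pixel_cutoff_high)
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("msi_diagnosis", class(out))
  out
}
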