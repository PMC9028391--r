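# Peak binning and construction of the three unit-level feature matrices
# (pixel, ROI, overall). Feature bins are learned once, on the training
# ROI-average peaks, and frozen for every other unit, preventing leakage of
# validation structure into the feature axis.

#' Bin peaks from many units into a shared feature matrix
#'
#' All peaks are pooled and sorted by m/z; a new bin starts wherever the gap
#' to the previous peak exceeds the relative tolerance (single linkage). The
#' representative feature m/z is the intensity-weighted mean of the member
#' peaks; a unit's value is the summed intensity of its peaks in the bin
#' (0 when absent). Rows are ordered by unit identifier, so the result is
#' invariant to the input order of units.
#'
#' @param peaks Tibble with columns `unit_id`, `mz`, `intensity` holding the
#'   picked peaks of every unit.
#' @param tolerance Relative m/z tolerance (default 0.002).
#' @param unit_level Label stored on the result (`"pixel"`, `"roi"`,
#'   `"overall"`).
#' @return An `msi_features` object: `values` (units x features matrix),
#'   `unit_ids`, `feature_mzs`, `unit_level`.
#' @export
bin_peaks <- function(peaks, tolerance = 0.002, unit_level = "roi") {
  if (!nrow(peaks)) abort("no features: all peak lists are empty")
  ord <- order(peaks$mz)
  mzs <- peaks$mz[ord]
  gap_starts <- c(TRUE, diff(mzs) > tolerance * mzs[-length(mzs)])
  bin <- cumsum(gap_starts)
  feature_mzs <- as.numeric(tapply(mzs * peaks$intensity[ord], bin, sum) /
                              tapply(peaks$intensity[ord], bin, sum))
  unit_ids <- sort(unique(peaks$unit_id))
  values <- matrix(0, length(unit_ids), length(feature_mzs),
                   dimnames = list(unit_ids, NULL))
  ui <- match(peaks$unit_id[ord], unit_ids)
  lin <- ui + (bin - 1L) * length(unit_ids)
  sums <- tapply(peaks$intensity[ord], lin, sum)
  values[as.integer(names(sums))] <- sums
  new_features(values, unit_ids, feature_mzs, unit_level)
}

new_features <- function(values, unit_ids, feature_mzs, unit_level,
                         meta = NULL) {
  if (is.unsorted(feature_mzs, strictly = TRUE)) {
    abort("feature m/z must be strictly increasing")
  }
  structure(list(values = values, unit_ids = unit_ids,
                 feature_mzs = feature_mzs, unit_level = unit_level,
                 meta = meta),
            class = "msi_features")
}

#' @export
print.msi_features <- function(x, ...) {
  cat("<msi_features> ", nrow(x$values), " ", x$unit_level, " units x ",
      length(x$feature_mzs), " m/z features\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.msi_features <- function(x, ...) x$values

#' Turn a feature matrix into a long tibble
#' @param x An `msi_features` object.
#' @param ... Unused.
#' @export
tidy.msi_features <- function(x, ...) {
  tibble::tibble(
    unit_id = rep(x$unit_ids, times = length(x$feature_mzs)),
    feature_mz = rep(x$feature_mzs, each = length(x$unit_ids)),
    value = as.vector(x$values)
  )
}

# Assign each peak of each unit to the nearest frozen feature (within the
# relative tolerance); unassigned peaks are discarded, absent features are 0.
apply_feature_bins <- function(peaks, feature_mzs, tolerance, unit_ids,
                               unit_level, meta = NULL) {
  values <- matrix(0, length(unit_ids), length(feature_mzs),
                   dimnames = list(unit_ids, NULL))
  if (nrow(peaks)) {
    j <- findInterval(peaks$mz, c(-Inf, feature_mzs[-1] -
                                    diff(feature_mzs) / 2))
    ok <- abs(peaks$mz - feature_mzs[j]) <= tolerance * feature_mzs[j]
    ui <- match(peaks$unit_id, unit_ids)
    use <- which(ok & !is.na(ui))
    if (length(use)) {
      lin <- ui[use] + (j[use] - 1L) * length(unit_ids)
      sums <- tapply(peaks$intensity[use], lin, sum)
      values[as.integer(names(sums))] <- sums
    }
  }
  new_features(values, unit_ids, feature_mzs, unit_level, meta)
}

# Preprocess one nodule and reduce it to peak lists at the three unit levels.
process_nodule <- function(nodule, cfg) {
  keep_cols <- trim_grid(nodule$mz, cfg)
  if (!length(keep_cols)) abort("m/z grid does not intersect the configured range")
  mz <- nodule$mz[keep_cols]
  res <- preprocess_matrix(nodule$intensity[, keep_cols, drop = FALSE], cfg)
  Y <- res$intensity
  retained <- res$retained

  pixel_peaks <- vector("list", nrow(Y))
  pixel_peaks[retained] <- cpp_pick_peaks(Y[retained, , drop = FALSE],
                                          cfg$peak_snr_threshold)

  rois <- nodule$rois
  roi_ids <- unique(rois$roi_id)
  roi_avg <- matrix(0, 0, length(mz))
  roi_labels <- character(0)
  kept_roi_ids <- character(0)
  for (rid in roi_ids) {
    sel <- rois[rois$roi_id == rid, ]
    rows <- match(paste(sel$x, sel$y), paste(nodule$coords$x, nodule$coords$y))
    rows <- rows[!is.na(rows) & retained[rows]]
    if (!length(rows)) next
    roi_avg <- rbind(roi_avg, colMeans(Y[rows, , drop = FALSE]))
    roi_labels <- c(roi_labels, sel$label[1])
    kept_roi_ids <- c(kept_roi_ids, rid)
  }
  roi_peaks <- if (nrow(roi_avg)) cpp_pick_peaks(roi_avg, cfg$peak_snr_threshold) else list()

  overall_peaks <- NULL
  if (any(retained)) {
    overall <- matrix(colMeans(Y[retained, , drop = FALSE]), nrow = 1)
    overall_peaks <- cpp_pick_peaks(overall, cfg$peak_snr_threshold)[[1]]
  }

  list(sample_id = nodule$sample_id, mz = mz,
       pixel_peaks = pixel_peaks, retained = retained,
       pixel_class = nodule$coords$pixel_class,
       coords = nodule$coords[c("x", "y")],
       n_excluded = sum(!retained),
       roi_ids = kept_roi_ids, roi_labels = roi_labels, roi_peaks = roi_peaks,
       overall_peaks = overall_peaks)
}

peaks_to_tibble <- function(pk, mz, unit_id) {
  if (is.null(pk) || !length(pk$index)) return(NULL)
  tibble::tibble(unit_id = unit_id, mz = mz[pk$index], intensity = pk$intensity)
}

#' Preprocess cohort samples and extract peak lists
#'
#' @param cohort An `msi_cohort`.
#' @param cfg An [preprocess_config()].
#' @param sample_ids Samples to process (default: all).
#' @return A list of per-sample peak summaries (class `msi_peakdata`).
#' @export
extract_peaks <- function(cohort, cfg = preprocess_config(),
                          sample_ids = NULL) {
  ids <- sample_ids %||% cohort$manifest$sample_id
  out <- lapply(ids, function(sid) process_nodule(get_nodule(cohort, sid), cfg))
  names(out) <- ids
  structure(out, class = "msi_peakdata")
}

roi_peak_tibble <- function(pd) {
  dplyr::bind_rows(lapply(pd, function(s) {
    dplyr::bind_rows(purrr::map2(s$roi_peaks, s$roi_ids,
                                 function(pk, rid) peaks_to_tibble(pk, s$mz, rid)))
  }))
}

roi_meta <- function(pd) {
  dplyr::bind_rows(lapply(pd, function(s) {
    if (!length(s$roi_ids)) return(NULL)
    tibble::tibble(unit_id = s$roi_ids, sample_id = s$sample_id,
                   label = s$roi_labels)
  }))
}

#' Build the pixel-, ROI- and overall-level feature matrices
#'
#' The feature bins are computed once from the peaks of the training
#' ROI-average spectra and then applied to all three unit levels, so the
#' matrices share a single feature axis.
#'
#' @param cohort An `msi_cohort` whose manifest has a `set` column with at
#'   least one `"training"` sample.
#' @param cfg An [preprocess_config()].
#' @param sample_ids Optional subset of samples (must include training
#'   samples, which define the bins).
#' @return List with elements `pixel`, `roi`, `overall` (each
#'   `msi_features`), plus `n_excluded_pixels`.
#' @export
build_unit_matrices <- function(cohort, cfg = preprocess_config(),
                                sample_ids = NULL) {
  pd <- extract_peaks(cohort, cfg, sample_ids)
  train_ids <- cohort$manifest$sample_id[cohort$manifest$set == "training"]
  train_ids <- intersect(names(pd), train_ids)
  if (!length(train_ids)) abort("no training samples available to learn feature bins")
  train_roi_peaks <- roi_peak_tibble(pd[train_ids])
  if (is.null(train_roi_peaks) || !nrow(train_roi_peaks)) {
    abort("no features: all training ROI peak lists are empty")
  }
  bins <- bin_peaks(train_roi_peaks, cfg$bin_tolerance, "roi")$feature_mzs
  unit_matrices(pd, bins, cfg)
}

# assemble the three unit-level matrices on a frozen feature axis
unit_matrices <- function(pd, bins, cfg) {
  rp <- roi_peak_tibble(pd)
  rmeta <- roi_meta(pd)
  roi <- apply_feature_bins(rp, bins, cfg$bin_tolerance, rmeta$unit_id,
                            "roi", rmeta)

  op <- dplyr::bind_rows(lapply(pd, function(s) {
    peaks_to_tibble(s$overall_peaks, s$mz, s$sample_id)
  }))
  has_overall <- vapply(pd, function(s) !is.null(s$overall_peaks), TRUE)
  ometa <- tibble::tibble(unit_id = names(pd)[has_overall],
                          sample_id = names(pd)[has_overall])
  overall <- apply_feature_bins(op, bins, cfg$bin_tolerance, ometa$unit_id,
                                "overall", ometa)

  pmeta <- dplyr::bind_rows(lapply(pd, function(s) {
    ret <- which(s$retained)
    if (!length(ret)) return(NULL)
    tibble::tibble(
      unit_id = sprintf("%s_px%05d", s$sample_id, ret),
      sample_id = s$sample_id,
      x = s$coords$x[ret], y = s$coords$y[ret],
      pixel_class = if (!is.null(s$pixel_class)) s$pixel_class[ret] else NA_character_
    )
  }))
  pp <- dplyr::bind_rows(lapply(pd, function(s) {
    ret <- which(s$retained)
    dplyr::bind_rows(purrr::map2(
      s$pixel_peaks[ret], sprintf("%s_px%05d", s$sample_id, ret),
      function(pk, uid) peaks_to_tibble(pk, s$mz, uid)
    ))
  }))
  pixel <- apply_feature_bins(pp, bins, cfg$bin_tolerance, pmeta$unit_id,
                              "pixel", pmeta)

  list(pixel = pixel, roi = roi, overall = overall,
       n_excluded_pixels = sum(vapply(pd, function(s) s$n_excluded, 0L)))
}
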