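# Cohort-level file formats: manifest CSV, ROI annotation CSV, pixel
# class-map PNG, and whole-cohort export/import (imzML per sample plus the
# two CSVs).

manifest_required_cols <- c("sample_id", "cytology", "truth", "subtype",
                            "cellularity")

#' Read a cohort manifest CSV
#'
#' Required columns: `sample_id`, `cytology` (TIR2-TIR5), `truth`
#' (benign/malignant/unknown), `subtype`, `cellularity`
#' (poor/good/optimal/unknown). Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return Tibble, one row per sample.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(manifest_required_cols, names(m))
  if (length(miss)) {
    abort(paste0("manifest lacks required columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(m$sample_id)) abort("duplicated sample_id in manifest")
  bad <- setdiff(m$cytology, c("TIR2", "TIR3", "TIR4", "TIR5"))
  if (length(bad)) abort(paste0("unknown cytology class: ", paste(bad, collapse = ", ")))
  bad <- setdiff(m$truth, c("benign", "malignant", "unknown"))
  if (length(bad)) abort(paste0("unknown truth label: ", paste(bad, collapse = ", ")))
  bad <- setdiff(m$cellularity, c("poor", "good", "optimal", "unknown"))
  if (length(bad)) abort(paste0("unknown cellularity grade: ", paste(bad, collapse = ", ")))
  m
}

#' Write a cohort manifest CSV
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read and validate ROI annotations
#'
#' CSV columns: `sample_id`, `roi_id`, `label`, `x`, `y`. Every ROI must be
#' nonempty, lie inside its sample's raster, and ROIs within a sample may
#' not overlap (overlap would silently double-count the ROI decision rule,
#' so it is an error naming the offending pair).
#'
#' @param path CSV path.
#' @param rasters Optional named list (by sample_id) of `c(width, height)`
#'   raster extents used for bounds checking.
#' @return Tibble of pixel-level ROI annotations.
#' @export
read_roi_annotations <- function(path, rasters = NULL) {
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("sample_id", "roi_id", "label", "x", "y"), names(r))
  if (length(miss)) {
    abort(paste0("ROI file lacks required columns: ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(r$label, c(msi_classes(), "unlabeled"))
  if (length(bad)) abort(paste0("unknown ROI label: ", paste(bad, collapse = ", ")))
  validate_rois(r, rasters)
  r
}

validate_rois <- function(rois, rasters = NULL) {
  for (sid in unique(rois$sample_id)) {
    rr <- rois[rois$sample_id == sid, ]
    if (!is.null(rasters) && !is.null(rasters[[sid]])) {
      ext <- rasters[[sid]]
      out <- rr$x < 1 | rr$x > ext[1] | rr$y < 1 | rr$y > ext[2]
      if (any(out)) {
        abort(sprintf("ROI pixel (%d,%d) outside %dx%d raster of %s",
                      rr$x[which(out)[1]], rr$y[which(out)[1]],
                      ext[1], ext[2], sid))
      }
    }
    key <- paste(rr$x, rr$y)
    dup <- duplicated(key)
    if (any(dup)) {
      k <- key[dup][1]
      pair <- unique(rr$roi_id[key == k])
      abort(paste0("overlapping ROIs in ", sid, ": ",
                   paste(pair, collapse = " and ")))
    }
  }
  invisible(rois)
}

roi_class_colors <- function() {
  c(HP = "#2CA02C", HT = "#F2C230", PTC = "#CC1F1F")
}

#' Write a pixel-by-pixel class map as a PNG image
#'
#' One image pixel per raster position: HP green, HT yellow, PTC red,
#' unclassified positions transparent.
#'
#' @param sample An `msi_nodule` (defines the raster extent).
#' @param calls Tibble with `x`, `y`, `class_call` for classified pixels.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_pixel_class_map <- function(sample, calls, path) {
  key <- paste(sample$coords$x, sample$coords$y)
  idx <- match(paste(calls$x, calls$y), key)
  if (anyNA(idx)) abort("class call for a pixel that is not in the sample")
  bad <- setdiff(unique(calls$class_call), msi_classes())
  if (length(bad)) abort(paste0("unknown class call: ", paste(bad, collapse = ", ")))
  w <- max(sample$coords$x)
  h <- max(sample$coords$y)
  img <- array(0, dim = c(h, w, 4))
  cols <- grDevices::col2rgb(roi_class_colors()) / 255
  for (i in seq_len(nrow(calls))) {
    rgbv <- cols[, calls$class_call[i]]
    img[calls$y[i], calls$x[i], ] <- c(rgbv, 1)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Export a cohort to disk (imzML + manifest + ROI annotations)
#'
#' Writes `manifest.csv`, `rois.csv` and one continuous-mode imzML/ibd pair
#' per sample into `dir`.
#'
#' @param cohort An `msi_cohort`.
#' @param dir Output directory (created if needed).
#' @param mode imzML mode, `"continuous"` (default) or `"processed"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, mode = "continuous") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  rois <- list()
  for (sid in cohort$manifest$sample_id) {
    nod <- get_nodule(cohort, sid)
    if (mode == "continuous") {
      write_imzml(list(mz = nod$mz, intensity = nod$intensity,
                       coords = nod$coords),
                  file.path(dir, paste0(sid, ".imzML")), mode = "continuous")
    } else {
      n <- nrow(nod$coords)
      write_imzml(list(mz = replicate(n, nod$mz, simplify = FALSE),
                       intensity = lapply(seq_len(n), function(i)
                         nod$intensity[i, ]),
                       coords = nod$coords),
                  file.path(dir, paste0(sid, ".imzML")), mode = "processed")
    }
    if (nrow(nod$rois)) rois[[sid]] <- nod$rois |>
        dplyr::mutate(sample_id = sid, .before = 1)
  }
  readr::write_csv(dplyr::bind_rows(rois), file.path(dir, "rois.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Expects the layout written by [write_cohort()]: `manifest.csv`,
#' `rois.csv` and one imzML per sample. Pixel data are read lazily, sample
#' by sample, when processed.
#'
#' @param dir Cohort directory.
#' @return An `msi_cohort` backed by files.
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  roi_file <- file.path(dir, "rois.csv")
  rois <- if (file.exists(roi_file)) {
    readr::read_csv(roi_file, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(manifest = manifest, dir = dir, rois = rois, files = TRUE),
            class = "msi_cohort")
}
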