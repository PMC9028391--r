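# Synthetic MSI cohort generation. One RNG stream per cohort is split
# hierarchically: the cohort seed draws one sub-seed per nodule (prefix-stable,
# so appending nodules never perturbs earlier ones) and each nodule's stream
# drives its cellularity draw, per-pixel peak dropout/jitter and noise.

mz_grid <- function(config) seq(config$mz_min, config$mz_max, by = config$mz_step)

baseline_curve <- function(noise, mz) {
  noise$baseline_amplitude * exp(-(mz - mz[1]) * noise$baseline_decay)
}

# rows = template peaks (heights included), columns = m/z grid; each Gaussian
# is only evaluated on a +/- 6 sigma window
gaussian_bank <- function(template, mz) {
  G <- matrix(0, nrow(template), length(mz))
  step <- if (length(mz) > 1) mz[2] - mz[1] else 1
  for (k in seq_len(nrow(template))) {
    s <- template$sigma[k]
    ctr <- template$peak_mz[k]
    j <- which(mz >= ctr - 6 * s & mz <= ctr + 6 * s)
    if (!length(j)) next
    G[k, j] <- template$height[k] * exp(-(mz[j] - ctr)^2 / (2 * s^2))
  }
  G
}

#' Simulate one pixel spectrum
#'
#' Intensity is the sum of the surviving template peaks (Gaussian in m/z),
#' an exponentially decaying baseline, and additive Gaussian noise; the total
#' is truncated at zero. With `template = NULL` a background-only (baseline
#' plus noise) pixel is produced.
#'
#' @param template An `msi_template` (one element of [make_class_templates()])
#'   or `NULL` for a background pixel.
#' @param noise An [noise_model()].
#' @param mz Sorted m/z grid covering the acquisition range.
#' @param rng_seed Optional seed; by default the current RNG stream is used.
#' @return Tibble with columns `mz` and `intensity`.
#' @export
simulate_pixel <- function(template, noise, mz, rng_seed = NULL) {
  if (!length(mz)) abort("`mz` grid must be nonempty")
  if (is.unsorted(mz, strictly = TRUE)) abort("`mz` grid must be strictly increasing")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  y <- baseline_curve(noise, mz)
  if (!is.null(template)) {
    G <- gaussian_bank(template, mz)
    k <- nrow(template)
    keep <- stats::rbinom(k, 1, 1 - noise$dropout_prob)
    cv <- noise$intensity_jitter_cv
    jit <- if (cv > 0) {
      s <- sqrt(log(1 + cv^2))
      rlnorm(k, meanlog = -s^2 / 2, sdlog = s)
    } else rep(1, k)
    y <- y + as.numeric((keep * jit) %*% G)
  }
  if (noise$additive_noise_sd > 0) {
    y <- y + rnorm(length(mz), 0, noise$additive_noise_sd)
  }
  tibble::tibble(mz = mz, intensity = pmax(y, 0))
}

simulate_block <- function(template, noise, mz, n_pix) {
  base <- baseline_curve(noise, mz)
  Y <- matrix(rep(base, each = n_pix), n_pix, length(mz))
  if (!is.null(template) && n_pix > 0) {
    G <- gaussian_bank(template, mz)
    k <- nrow(template)
    keep <- matrix(stats::rbinom(n_pix * k, 1, 1 - noise$dropout_prob), n_pix, k)
    cv <- noise$intensity_jitter_cv
    jit <- if (cv > 0) {
      s <- sqrt(log(1 + cv^2))
      matrix(rlnorm(n_pix * k, -s^2 / 2, s), n_pix, k)
    } else matrix(1, n_pix, k)
    Y <- Y + (keep * jit) %*% G
  }
  if (noise$additive_noise_sd > 0 && n_pix > 0) {
    Y <- Y + matrix(rnorm(n_pix * length(mz), 0, noise$additive_noise_sd),
                    n_pix, length(mz))
  }
  Y[Y < 0] <- 0
  Y
}

#' Simulate a single nodule sample
#'
#' Pixels are laid out row-major on a near-square raster. The cellularity
#' grade fixes the fraction of informative (template-bearing) pixels (poor
#' 20-30%, good 30-70%, optimal >70%); the remaining pixels carry only
#' baseline and noise. Informative pixels are assigned to phenotype classes
#' in contiguous runs according to `composition`, and single-class
#' rectangular ROIs are carved from full raster rows inside each run.
#'
#' @param truth_label `"benign"` or `"malignant"` (recorded, not used in
#'   spectra generation; the spectra follow `composition`).
#' @param composition Named fractions (classes HP/HT/PTC) summing to 1 that
#'   partition the informative pixels.
#' @param config An [cohort_config()].
#' @param templates Output of [make_class_templates()].
#' @param rng_seed Integer seed for this nodule.
#' @param cellularity `"poor"`, `"good"` or `"optimal"`.
#' @param sample_id Identifier stored on the result.
#' @param roi_counts Optional named integer vector of ROIs per class; by
#'   default `config$rois_per_nodule` ROIs are split proportionally to the
#'   class pixel counts.
#' @return An `msi_nodule` list: `mz`, `intensity` (pixels x grid matrix),
#'   `coords` (tibble `x`, `y`, `pixel_class`), `rois` (tibble `roi_id`,
#'   `label`, `x`, `y`), `informative_fraction`.
#' @export
simulate_nodule <- function(truth_label, composition, config, templates,
                            rng_seed, cellularity = "optimal",
                            sample_id = "S001", roi_counts = NULL) {
  if (abs(sum(composition) - 1) > 1e-9) {
    abort("composition fractions must sum to 1")
  }
  bad <- setdiff(names(composition), msi_classes())
  if (length(bad)) abort(paste0("unknown composition class: ", paste(bad, collapse = ", ")))
  if (!truth_label %in% c("benign", "malignant")) {
    abort("`truth_label` must be benign or malignant")
  }
  set.seed(rng_seed)
  mz <- mz_grid(config)
  n <- config$pixels_per_nodule
  w <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  coords <- tibble::tibble(x = idx %% w + 1L, y = idx %/% w + 1L)

  band <- cellularity_band(cellularity)
  inf_frac <- runif(1, band[1], band[2])
  n_inf <- round(inf_frac * n)

  cls <- intersect(msi_classes(), names(composition))
  counts <- alloc_largest_remainder(composition[cls], n_inf)
  names(counts) <- cls
  pixel_class <- c(rep(cls, counts), rep("background", n - n_inf))
  coords$pixel_class <- pixel_class

  # ROIs: full raster rows inside each single-class run
  if (is.null(roi_counts)) {
    roi_counts <- alloc_largest_remainder(counts, config$rois_per_nodule)
    names(roi_counts) <- cls
  }
  rois <- build_rois(counts, roi_counts, w, config$roi_min_pixels, sample_id)

  Y <- matrix(0, n, length(mz))
  start <- 1L
  for (k in seq_along(cls)) {
    if (counts[k] == 0) next
    rows <- start:(start + counts[k] - 1L)
    Y[rows, ] <- simulate_block(templates[[cls[k]]], config$noise, mz, counts[k])
    start <- start + counts[k]
  }
  if (n_inf < n) {
    Y[(n_inf + 1L):n, ] <- simulate_block(NULL, config$noise, mz, n - n_inf)
  }

  structure(list(sample_id = sample_id, truth_label = truth_label,
                 cellularity = cellularity, mz = mz, intensity = Y,
                 coords = coords, rois = rois,
                 informative_fraction = inf_frac, raster_width = w),
            class = "msi_nodule")
}

build_rois <- function(counts, roi_counts, w, roi_min_pixels, sample_id) {
  out <- list()
  bounds <- cumsum(c(0L, counts))
  rows_per_roi <- max(1L, ceiling(roi_min_pixels / w))
  roi_i <- 0L
  for (k in seq_along(counts)) {
    want <- if (names(counts)[k] %in% names(roi_counts)) {
      roi_counts[[names(counts)[k]]]
    } else 0L
    if (want == 0L || counts[k] == 0L) next
    a <- bounds[k] + 1L
    b <- bounds[k + 1L]
    first_row <- ceiling((a - 1L) / w) + 1L   # first fully-contained row
    last_row <- b %/% w                       # last fully-contained row
    blocks <- list()
    if (last_row >= first_row) {
      avail <- first_row:last_row
      n_blocks <- length(avail) %/% rows_per_roi
      blocks <- lapply(seq_len(n_blocks), function(i) {
        avail[((i - 1L) * rows_per_roi + 1L):(i * rows_per_roi)]
      })
    }
    if (length(blocks)) {
      pick <- unique(round(seq(1, length(blocks), length.out = min(want, length(blocks)))))
      for (p in pick) {
        roi_i <- roi_i + 1L
        rows <- blocks[[p]]
        px <- as.vector(outer(seq_len(w), (rows - 1L) * w, `+`))
        out[[length(out) + 1L]] <- tibble::tibble(
          roi_id = sprintf("%s_R%02d", sample_id, roi_i),
          label = names(counts)[k],
          x = (px - 1L) %% w + 1L, y = (px - 1L) %/% w + 1L
        )
      }
    } else if (b - a + 1L >= 2L) {
      # degenerate fallback for tiny runs: the run itself as one ROI
      roi_i <- roi_i + 1L
      px <- a:b
      out[[length(out) + 1L]] <- tibble::tibble(
        roi_id = sprintf("%s_R%02d", sample_id, roi_i),
        label = names(counts)[k],
        x = (px - 1L) %% w + 1L, y = (px - 1L) %/% w + 1L
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(roi_id = character(), label = character(),
                          x = integer(), y = integer()))
  }
  dplyr::bind_rows(out)
}

#' Simulate a full training + validation cohort
#'
#' Builds the manifest from the configured design (default: 70 training
#' nodules, 40 HP + 10 HT + 20 PTC, and 170 validation nodules split
#' 33/77/19/41 across TIR2-TIR5), draws one sub-seed per nodule and returns
#' a lazy cohort object: pixel data are materialized per sample with
#' [get_nodule()], so arbitrarily large cohorts stay cheap until processed.
#'
#' @param config An [cohort_config()].
#' @param roi_targets Optional named totals of ROIs per class (e.g.
#'   `c(HP = 381, HT = 50, PTC = 174)`) distributed over the training
#'   nodules whose dominant phenotype matches.
#' @return An `msi_cohort` list with elements `manifest`, `templates`,
#'   `config`, `sample_seeds`, `roi_counts`.
#' @export
simulate_cohort <- function(config = cohort_config(), roi_targets = NULL) {
  templates <- make_class_templates(
    rng_seed = config$rng_seed,
    n_peaks_per_class = config$n_peaks_per_class,
    shared_peak_fraction = config$shared_peak_fraction,
    mz_range = c(config$mz_min, config$mz_max)
  )
  manifest <- design_manifest(config)
  set.seed(config$rng_seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(manifest))

  roi_counts <- NULL
  if (!is.null(roi_targets)) {
    roi_counts <- allocate_roi_targets(roi_targets, manifest)
  }

  structure(list(manifest = manifest, templates = templates, config = config,
                 sample_seeds = setNames(sample_seeds, manifest$sample_id),
                 roi_counts = roi_counts),
            class = "msi_cohort")
}

# distribute per-class ROI totals over the training nodules dominated by
# that class (HP ROIs to HP nodules, etc.)
allocate_roi_targets <- function(targets, manifest) {
  tr <- manifest[manifest$set == "training", ]
  dominant <- ifelse(tr$truth == "malignant", "PTC",
                     ifelse(tr$subtype == "HT", "HT", "HP"))
  out <- setNames(vector("list", nrow(manifest)), manifest$sample_id)
  for (cl in names(targets)) {
    ids <- tr$sample_id[dominant == cl]
    if (!length(ids)) abort(paste0("no training nodule can host ", cl, " ROIs"))
    per <- rep(targets[[cl]] %/% length(ids), length(ids))
    extra <- targets[[cl]] %% length(ids)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    for (i in seq_along(ids)) {
      out[[ids[i]]] <- c(out[[ids[i]]], setNames(per[i], cl))
    }
  }
  out
}

#' Materialize the pixel data of one cohort sample
#'
#' @param cohort An `msi_cohort`.
#' @param sample_id Sample identifier from the manifest.
#' @return An `msi_nodule` (see [simulate_nodule()]).
#' @export
get_nodule <- function(cohort, sample_id) {
  stopifnot(inherits(cohort, "msi_cohort"))
  row <- cohort$manifest[cohort$manifest$sample_id == sample_id, ]
  if (nrow(row) != 1) abort(paste0("unknown sample_id: ", sample_id))
  if (isTRUE(cohort$files)) {
    dat <- read_imzml(file.path(cohort$dir, paste0(sample_id, ".imzML")))
    rois <- if (!is.null(cohort$rois)) {
      cohort$rois[cohort$rois$sample_id == sample_id,
                  c("roi_id", "label", "x", "y")]
    } else {
      tibble::tibble(roi_id = character(), label = character(),
                     x = integer(), y = integer())
    }
    coords <- dat$coords
    coords$pixel_class <- NA_character_
    return(structure(list(sample_id = sample_id, truth_label = row$truth,
                          cellularity = row$cellularity, mz = dat$mz,
                          intensity = dat$intensity, coords = coords,
                          rois = rois, informative_fraction = NA_real_,
                          raster_width = max(coords$x)),
                     class = "msi_nodule"))
  }
  comp <- sample_composition(row$set, row$truth, row$subtype, cohort$config)
  simulate_nodule(
    truth_label = row$truth, composition = comp, config = cohort$config,
    templates = cohort$templates, rng_seed = cohort$sample_seeds[[sample_id]],
    cellularity = row$cellularity, sample_id = sample_id,
    roi_counts = if (!is.null(cohort$roi_counts)) cohort$roi_counts[[sample_id]]
  )
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat("<msi_cohort> ", nrow(x$manifest), " samples (",
      sum(x$manifest$set == "training"), " training / ",
      sum(x$manifest$set == "validation"), " validation), ",
      x$config$pixels_per_nodule, " pixels per nodule, m/z ",
      x$config$mz_min, "-", x$config$mz_max, "\n", sep = "")
  invisible(x)
}
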