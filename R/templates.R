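#' Spectral class templates for the three thyroid phenotypes
#'
#' Builds one peak template per class (HP, HT, PTC) on the linear-positive
#' MALDI acquisition range. A configurable fraction of peaks is shared by all
#' three classes, the two benign classes (HP, HT) share additional peaks with
#' each other, and every class keeps at least one private peak so that the
#' classes remain separable in principle.
#'
#' @param rng_seed Integer seed; templates are fully reproducible.
#' @param n_peaks_per_class Number of peaks per class template (>= 2).
#' @param shared_peak_fraction Fraction in `[0, 1)` of each template shared by
#'   all classes. `0` yields pairwise-disjoint peak sets.
#' @param mz_range Acquisition window in Da (default 3000-15000).
#' @param height_range Range of relative peak heights drawn uniformly.
#' @param min_separation Minimum distance in Da between distinct peak
#'   positions, so peaks stay resolvable after smoothing.
#' @param ensure_unique If `TRUE` (default) error when the sharing scheme
#'   would leave a class without a private peak.
#' @return Named list of three `msi_template` tibbles (columns `peak_mz`,
#'   `height`, `sigma`), one per class.
#' @examples
#' tpl <- make_class_templates(1, n_peaks_per_class = 6, shared_peak_fraction = 0.3)
#' tpl$PTC
#' @export
make_class_templates <- function(rng_seed, n_peaks_per_class = 10,
                                 shared_peak_fraction = 0.3,
                                 mz_range = c(3000, 15000),
                                 height_range = c(40, 120),
                                 min_separation = 80,
                                 ensure_unique = TRUE) {
  stop_if_not_scalar_count(n_peaks_per_class, "n_peaks_per_class")
  if (n_peaks_per_class < 2) abort("`n_peaks_per_class` must be >= 2")
  if (!is.numeric(shared_peak_fraction) || length(shared_peak_fraction) != 1 ||
      shared_peak_fraction < 0 || shared_peak_fraction >= 1) {
    abort("`shared_peak_fraction` must be in [0, 1)")
  }

  n <- n_peaks_per_class
  n_common <- floor(shared_peak_fraction * n)
  n_benign <- if (shared_peak_fraction > 0) max(1L, floor(n_common / 2)) else 0L
  n_unique_benign <- n - n_common - n_benign
  n_unique_ptc <- n - n_common
  if (ensure_unique && (n_unique_benign < 1 || n_unique_ptc < 1)) {
    abort("sharing scheme leaves a class without a private peak")
  }

  n_positions <- n_common + n_benign + 2 * n_unique_benign + n_unique_ptc
  set.seed(rng_seed)
  positions <- draw_separated_positions(
    n_positions, mz_range[1] + 500, mz_range[2] - 500, min_separation
  )

  take <- function(k) {
    if (k == 0) return(numeric(0))
    out <- positions[seq_len(k)]
    positions <<- positions[-seq_len(k)]
    out
  }
  common <- take(n_common)
  benign_shared <- take(n_benign)
  uniq <- list(HP = take(n_unique_benign), HT = take(n_unique_benign),
               PTC = take(n_unique_ptc))

  build <- function(label) {
    mzs <- switch(label,
      HP = c(common, benign_shared, uniq$HP),
      HT = c(common, benign_shared, uniq$HT),
      PTC = c(common, uniq$PTC)
    )
    mzs <- sort(mzs)
    tpl <- tibble::tibble(
      peak_mz = mzs,
      height = runif(length(mzs), height_range[1], height_range[2]),
      sigma = 2 * mzs / 5000
    )
    structure(tpl, class = c("msi_template", class(tpl)),
              class_label = label, mz_range = mz_range)
  }
  out <- lapply(setNames(msi_classes(), msi_classes()), build)
  for (t in out) validate_template(t)
  out
}

draw_separated_positions <- function(k, lo, hi, min_sep) {
  chosen <- numeric(0)
  tries <- 0
  while (length(chosen) < k) {
    cand <- round(runif(1, lo, hi))
    if (!length(chosen) || min(abs(chosen - cand)) >= min_sep) {
      chosen <- c(chosen, cand)
    }
    tries <- tries + 1
    if (tries > 10000 * k) abort("cannot place peaks with requested separation")
  }
  chosen
}

validate_template <- function(tpl) {
  rng <- attr(tpl, "mz_range") %||% c(3000, 15000)
  if (any(tpl$peak_mz < rng[1] | tpl$peak_mz > rng[2])) {
    abort("template peaks outside acquisition range")
  }
  if (any(tpl$height <= 0)) abort("template peak heights must be positive")
  if (is.unsorted(tpl$peak_mz, strictly = TRUE)) {
    abort("template peak m/z must be strictly increasing")
  }
  invisible(tpl)
}

#' Pixel-level noise model for synthetic spectra
#'
#' Describes the departures of a measured pixel spectrum from its pure class
#' template: a chemical-background baseline decaying exponentially with m/z,
#' additive detector noise (truncated at zero intensity), multiplicative
#' per-peak intensity jitter, and whole-peak dropout emulating poor or noisy
#' pixels.
#'
#' @param baseline_amplitude Baseline intensity at the low-mass edge (>= 0).
#' @param baseline_decay Exponential decay constant in 1/Da (>= 0).
#' @param additive_noise_sd Standard deviation of additive noise (>= 0).
#' @param intensity_jitter_cv Coefficient of variation in `[0, 1)` of the
#'   log-normal multiplicative jitter applied per peak and pixel.
#' @param dropout_prob Probability in `[0, 1)` that a template peak is absent
#'   from a given pixel.
#' @return An `msi_noise` list.
#' @export
noise_model <- function(baseline_amplitude = 8, baseline_decay = 1 / 2000,
                        additive_noise_sd = 1, intensity_jitter_cv = 0.15,
                        dropout_prob = 0.03) {
  vals <- c(baseline_amplitude = baseline_amplitude,
            baseline_decay = baseline_decay,
            additive_noise_sd = additive_noise_sd,
            intensity_jitter_cv = intensity_jitter_cv,
            dropout_prob = dropout_prob)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all noise model fields must be finite and nonnegative")
  }
  if (dropout_prob >= 1) abort("`dropout_prob` must be < 1")
  if (intensity_jitter_cv >= 1) abort("`intensity_jitter_cv` must be < 1")
  structure(as.list(vals), class = "msi_noise")
}

#' Cohort design configuration for the synthetic generator
#'
#' Fixes the study design that the generator reproduces: training counts of
#' 40 HP + 10 HT + 20 PTC nodules (all with good/optimal cellularity) and a
#' 170-sample validation series split 33/77/19/41 across the TIR2-TIR5
#' cytology tiers. Cellularity grades map to the fraction of informative
#' (thyrocyte-bearing) pixels: poor 20-30%, good 30-70%, optimal >70%.
#'
#' @param n_hp_train,n_ht_train,n_ptc_train Training nodule counts per class.
#' @param validation_cytology Named counts for TIR2-TIR5 validation samples.
#' @param pixels_per_nodule Pixels on the raster of each nodule.
#' @param rois_per_nodule Annotated regions of interest per nodule.
#' @param roi_min_pixels Minimum pixels per ROI (rectangular blocks).
#' @param malignant_fraction_train Fraction of informative pixels carrying the
#'   PTC phenotype in training carcinomas (default 0.9, matching the high
#'   malignant-pixel content of training samples).
#' @param malignant_fraction_validation The same fraction for validation
#'   malignancies (default 0.5; validation nodules carry tumor cells in an
#'   otherwise benign background).
#' @param borderline_fraction PTC admixture given to borderline benign
#'   histologies (FA, NIFTP, WDT-UMP), which share features of both groups.
#' @param mz_min,mz_max,mz_step Common m/z grid (Da).
#' @param n_peaks_per_class,shared_peak_fraction Passed to
#'   [make_class_templates()].
#' @param noise An [noise_model()] object.
#' @param rng_seed Integer seed for the whole cohort.
#' @return An `msi_config` list.
#' @export
cohort_config <- function(n_hp_train = 40, n_ht_train = 10, n_ptc_train = 20,
                          validation_cytology = c(TIR2 = 33, TIR3 = 77,
                                                  TIR4 = 19, TIR5 = 41),
                          pixels_per_nodule = 500,
                          rois_per_nodule = 6,
                          roi_min_pixels = 20,
                          malignant_fraction_train = 0.9,
                          malignant_fraction_validation = 0.5,
                          borderline_fraction = 0.15,
                          mz_min = 3000, mz_max = 15000, mz_step = 1,
                          n_peaks_per_class = 10, shared_peak_fraction = 0.3,
                          noise = noise_model(),
                          rng_seed = 1L) {
  for (nm in c("n_hp_train", "n_ht_train", "n_ptc_train", "pixels_per_nodule",
               "rois_per_nodule", "roi_min_pixels")) {
    stop_if_not_scalar_count(get(nm), nm)
  }
  if (is.null(names(validation_cytology)) ||
      !all(c("TIR2", "TIR3", "TIR4", "TIR5") %in% names(validation_cytology))) {
    abort("`validation_cytology` must be named TIR2..TIR5")
  }
  if (any(validation_cytology < 0)) abort("validation counts must be nonnegative")
  for (f in c(malignant_fraction_train, malignant_fraction_validation,
              borderline_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort("malignant pixel fractions must be in [0, 1]")
    }
  }
  if (mz_min >= mz_max || mz_step <= 0) abort("invalid m/z grid")
  stopifnot(inherits(noise, "msi_noise"))
  structure(list(
    n_hp_train = n_hp_train, n_ht_train = n_ht_train, n_ptc_train = n_ptc_train,
    validation_cytology = validation_cytology[c("TIR2", "TIR3", "TIR4", "TIR5")],
    pixels_per_nodule = pixels_per_nodule, rois_per_nodule = rois_per_nodule,
    roi_min_pixels = roi_min_pixels,
    malignant_fraction_train = malignant_fraction_train,
    malignant_fraction_validation = malignant_fraction_validation,
    borderline_fraction = borderline_fraction,
    mz_min = mz_min, mz_max = mz_max, mz_step = mz_step,
    n_peaks_per_class = n_peaks_per_class,
    shared_peak_fraction = shared_peak_fraction,
    noise = noise, rng_seed = as.integer(rng_seed)
  ), class = "msi_config")
}

cellularity_band <- function(grade) {
  switch(grade,
    poor = c(0.20, 0.30),
    good = c(0.30, 0.70),
    optimal = c(0.70, 1.00),
    abort(paste0("unknown cellularity grade: ", grade))
  )
}
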