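# Shared fixtures. All cohorts here are deliberately small; the full-size
# design is exercised in test-acceptance.R.

# noiseless: no baseline, no additive noise, no jitter/dropout, so background
# pixels have zero TIC and informative pixels are exact template mixtures
noiseless_noise <- function() {
  noise_model(baseline_amplitude = 0, baseline_decay = 0,
              additive_noise_sd = 0, intensity_jitter_cv = 0,
              dropout_prob = 0)
}

small_config <- function(rng_seed = 11, pixels_per_nodule = 150,
                         rois_per_nodule = 4, roi_min_pixels = 10, ...) {
  cohort_config(
    n_hp_train = 3, n_ht_train = 2, n_ptc_train = 3,
    validation_cytology = c(TIR2 = 3, TIR3 = 3, TIR4 = 1, TIR5 = 3),
    pixels_per_nodule = pixels_per_nodule, rois_per_nodule = rois_per_nodule,
    roi_min_pixels = roi_min_pixels, mz_step = 2, rng_seed = rng_seed, ...
  )
}

# a separable, noiseless cohort: disjoint class peak sets, zero noise, and
# no borderline admixture (pure-class benign nodules)
noiseless_config <- function(..., rng_seed = 11) {
  small_config(shared_peak_fraction = 0, noise = noiseless_noise(),
               borderline_fraction = 0, rng_seed = rng_seed, ...)
}

# direct, linearly separable ROI feature matrix: class k loads on its own
# block of features
separable_roi_matrix <- function(n_per_class = 10, seed = 1) {
  set.seed(seed)
  cls <- rep(c("HP", "HT", "PTC"), each = n_per_class)
  x <- matrix(0, length(cls), 9)
  for (i in seq_along(cls)) {
    block <- (match(cls[i], c("HP", "HT", "PTC")) - 1) * 3 + 1:3
    x[i, block] <- abs(rnorm(3, 5, 0.5))
    x[i, -block] <- abs(rnorm(6, 0, 0.05))
  }
  list(x = x, labels = cls)
}

# independent brute-force oracle for cutoff selection: enumerate every
# candidate and score it directly
oracle_candidates <- function(v) {
  s <- sort(unique(v))
  d <- if (length(s) > 1) min(diff(s)) / 2 else 1e-3
  c(s[1] - d, if (length(s) > 1) head(s, -1) + diff(s) / 2, s[length(s)] + d)
}

oracle_youden <- function(fraction, truth) {
  cand <- oracle_candidates(fraction)
  best_j <- -Inf
  best_c <- NA
  for (c in cand) {
    sens <- mean(fraction[truth == "malignant"] > c)
    spec <- mean(fraction[truth == "benign"] <= c)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- c
    }
  }
  list(cutoff = best_c, j = best_j)
}

# swap validation cellularity to a single grade, keeping all sample seeds
with_grade <- function(cohort, grade) {
  val <- cohort$manifest$set == "validation"
  cohort$manifest$cellularity[val] <- grade
  cohort
}
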