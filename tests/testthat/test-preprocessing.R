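gauss_spec <- function(mz, centers, heights, sigma = 6) {
  y <- rowSums(sapply(seq_along(centers), function(k) {
    heights[k] * exp(-(mz - centers[k])^2 / (2 * sigma^2))
  }))
  tibble::tibble(mz = mz, intensity = y)
}

test_that("baseline subtraction absorbs constant spectra", {
  mz <- seq(3000, 15000, by = 1)
  flat <- tibble::tibble(mz = mz, intensity = rep(40, length(mz)))
  out <- preprocess_spectrum(flat, preprocess_config(normalization = "none"))
  expect_lte(max(out$intensity), 1e-9 * 40)
  expect_true(isTRUE(attr(out, "empty"))) # nothing left after baseline
})

test_that("TIC normalization makes intensities sum to one", {
  mz <- seq(3000, 15000, by = 2)
  spec <- gauss_spec(mz, c(5000, 8000, 12000), c(80, 50, 30))
  out <- preprocess_spectrum(spec, preprocess_config())
  expect_equal(sum(out$intensity), 1, tolerance = 1e-9)
  expect_false(isTRUE(attr(out, "empty")))
})

test_that("peak apexes survive preprocessing within one grid step", {
  mz <- seq(3000, 15000, by = 2)
  centers <- c(5000, 8000, 12000)
  spec <- gauss_spec(mz, centers, c(80, 50, 30))
  out <- preprocess_spectrum(spec, preprocess_config())
  pks <- pick_peaks(out, preprocess_config())
  expect_equal(nrow(pks), 3)
  expect_true(all(abs(sort(pks$mz) - centers) <= 2))
})

test_that("peak picking handles degenerate spectra and thresholds", {
  mz <- seq(3000, 4000, by = 1)
  zero <- tibble::tibble(mz = mz, intensity = rep(0, length(mz)))
  expect_equal(nrow(pick_peaks(zero, preprocess_config())), 0)

  # a lone Gaussian at SNR ~50: the apex dominates every noise bump, and a
  # stringent SNR threshold isolates exactly that one peak
  set.seed(7)
  spec <- gauss_spec(mz, 3500, 50, sigma = 6)
  spec$intensity <- pmax(spec$intensity + rnorm(length(mz), 0, 1), 0)
  cfg <- preprocess_config(normalization = "none", mz_range = range(mz))
  out <- preprocess_spectrum(spec, cfg)
  pks <- pick_peaks(out, cfg)
  expect_gte(nrow(pks), 1)
  expect_lte(abs(pks$mz[which.max(pks$intensity)] - 3500), 1)
  strict <- pick_peaks(out, preprocess_config(
    peak_snr_threshold = 20, normalization = "none", mz_range = range(mz)))
  expect_equal(nrow(strict), 1)
  expect_lte(abs(strict$mz - 3500), 1)
  # monotone in the threshold, down to the empty set
  expect_lte(nrow(strict), nrow(pks))
  expect_equal(nrow(pick_peaks(out, preprocess_config(
    peak_snr_threshold = Inf, mz_range = range(mz)))), 0)
})

test_that("binning merges within tolerance, splits beyond, order-invariant", {
  peaks <- tibble::tibble(unit_id = c("a", "b"),
                          mz = c(5000, 5005), intensity = c(2, 1))
  fm <- bin_peaks(peaks, 0.002)
  expect_length(fm$feature_mzs, 1)
  # intensity-weighted representative m/z
  expect_equal(fm$feature_mzs, (5000 * 2 + 5005) / 3)
  expect_equal(as.vector(fm$values), c(2, 1))

  far <- tibble::tibble(unit_id = c("a", "b"), mz = c(5000, 6000),
                        intensity = c(1, 1))
  expect_length(bin_peaks(far, 0.002)$feature_mzs, 2)

  expect_error(bin_peaks(tibble::tibble(unit_id = character(),
                                        mz = numeric(),
                                        intensity = numeric())),
               "no features")

  set.seed(3)
  many <- tibble::tibble(
    unit_id = sample(letters[1:6], 60, replace = TRUE),
    mz = runif(60, 3000, 15000), intensity = runif(60, 1, 5))
  f1 <- bin_peaks(many, 0.002)
  f2 <- bin_peaks(many[sample(60), ], 0.002)
  expect_equal(f1$feature_mzs, f2$feature_mzs)
  expect_equal(f1$unit_ids, f2$unit_ids)
  expect_equal(f1$values, f2$values)
})

test_that("average_spectrum is the pointwise mean and preserves TIC", {
  mz <- seq(3000, 3500, by = 1)
  s1 <- tibble::tibble(mz = mz, intensity = runif(length(mz)))
  expect_equal(average_spectrum(list(s1)), s1)
  expect_equal(average_spectrum(list(s1, s1)), s1)

  norm <- function(s) { s$intensity <- s$intensity / sum(s$intensity); s }
  s2 <- tibble::tibble(mz = mz, intensity = runif(length(mz)))
  avg <- average_spectrum(list(norm(s1), norm(s2)))
  expect_equal(sum(avg$intensity), 1, tolerance = 1e-9)

  expect_error(average_spectrum(list()), "empty")
  s3 <- s2
  s3$mz <- s3$mz + 0.5
  expect_error(average_spectrum(list(s1, s3)), "common")
})

test_that("repeated preprocessing is near-stationary on clean spectra", {
  mz <- seq(3000, 15000, by = 2)
  spec <- gauss_spec(mz, c(5000, 8000, 12000), c(80, 50, 30), sigma = 12)
  cfg <- preprocess_config()
  once <- preprocess_spectrum(spec, cfg)
  twice <- preprocess_spectrum(once, cfg)
  first_change <- max(abs(once$intensity - spec$intensity / sum(spec$intensity)))
  second_change <- max(abs(twice$intensity - once$intensity))
  # smoothing is not a projection and SNIP keeps clipping, so a second pass
  # is not a fixed point; it must however drift far less than the first
  expect_lt(second_change / max(once$intensity), 0.10)
  expect_lt(second_change, first_change)
})

test_that("unit matrices share one feature axis with conserved row counts", {
  cfg <- small_config(rng_seed = 19)
  co <- simulate_cohort(cfg)
  pc <- preprocess_config()
  mats <- build_unit_matrices(co, pc)
  expect_identical(mats$pixel$feature_mzs, mats$roi$feature_mzs)
  expect_identical(mats$roi$feature_mzs, mats$overall$feature_mzs)
  # training ROI matrix has no all-zero feature column (bins built from it)
  tr_rois <- mats$roi$meta$sample_id %in%
    co$manifest$sample_id[co$manifest$set == "training"]
  expect_true(all(colSums(mats$roi$values[tr_rois, ]) > 0))
  # row counts: one per retained pixel / ROI / sample
  n_pix <- sum(vapply(co$manifest$sample_id, function(sid) {
    pd <- thyromsi:::process_nodule(get_nodule(co, sid), pc)
    sum(pd$retained)
  }, 0))
  expect_equal(nrow(mats$pixel$values), n_pix)
  expect_equal(nrow(mats$overall$values), nrow(co$manifest))
})

test_that("single-sample cohorts yield one-row ROI and overall matrices", {
  cfg <- cohort_config(n_hp_train = 1, n_ht_train = 0, n_ptc_train = 0,
                       validation_cytology = c(TIR2 = 0, TIR3 = 0,
                                               TIR4 = 0, TIR5 = 0),
                       pixels_per_nodule = 100, rois_per_nodule = 1,
                       roi_min_pixels = 10, mz_step = 2, rng_seed = 3)
  co <- simulate_cohort(cfg)
  mats <- build_unit_matrices(co)
  expect_equal(nrow(mats$roi$values), 1)
  expect_equal(nrow(mats$overall$values), 1)
})
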