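test_that("class templates honor the construction contract", {
  tpl <- make_class_templates(1, n_peaks_per_class = 10,
                              shared_peak_fraction = 0.3)
  expect_named(tpl, c("HP", "HT", "PTC"))
  for (t in tpl) {
    expect_equal(nrow(t), 10)
    expect_true(all(t$peak_mz >= 3000 & t$peak_mz <= 15000))
    expect_true(all(diff(t$peak_mz) > 0))
    expect_true(all(t$height > 0))
  }
  # every class keeps at least one private peak
  for (cl in names(tpl)) {
    others <- unlist(lapply(tpl[setdiff(names(tpl), cl)], `[[`, "peak_mz"))
    expect_gte(sum(!tpl[[cl]]$peak_mz %in% others), 1)
  }
  # the two benign classes share more peaks with each other than with PTC
  shared <- function(a, b) length(intersect(tpl[[a]]$peak_mz, tpl[[b]]$peak_mz))
  expect_gt(shared("HP", "HT"), shared("HP", "PTC"))
  expect_gt(shared("HP", "HT"), shared("HT", "PTC"))

  expect_identical(tpl, make_class_templates(1, 10, 0.3))

  disj <- make_class_templates(2, 8, 0)
  expect_true(all(vapply(disj, nrow, 0L) == 8L))
  expect_length(intersect(disj$HP$peak_mz, disj$HT$peak_mz), 0)
  expect_length(intersect(disj$HP$peak_mz, disj$PTC$peak_mz), 0)
  expect_length(intersect(disj$HT$peak_mz, disj$PTC$peak_mz), 0)

  expect_error(make_class_templates(1, 10, 1.2), "shared_peak_fraction")
  expect_error(make_class_templates(1, 1, 0), "n_peaks_per_class")
})

test_that("noiseless pixels equal the pure Gaussian mixture", {
  tpl <- make_class_templates(3, 5, 0)
  mz <- seq(3000, 15000, by = 1)
  nz <- noiseless_noise()
  px <- simulate_pixel(tpl$PTC, nz, mz, rng_seed = 1)
  # apex intensities match template heights where the grid hits the apex
  apex <- match(tpl$PTC$peak_mz, mz)
  expect_true(all(abs(px$intensity[apex] - tpl$PTC$height) < 1e-9))
  expect_true(all(px$intensity >= 0))

  # full dropout leaves only the baseline
  drop_all <- noise_model(baseline_amplitude = 5, baseline_decay = 1e-4,
                          additive_noise_sd = 0, intensity_jitter_cv = 0,
                          dropout_prob = 1 - 1e-12)
  px2 <- simulate_pixel(tpl$PTC, drop_all, mz, rng_seed = 1)
  expect_equal(px2$intensity, 5 * exp(-(mz - 3000) * 1e-4), tolerance = 1e-9)

  expect_error(simulate_pixel(tpl$PTC, nz, numeric()), "nonempty")
})

test_that("replicate pixel mean matches the truncated-normal expectation", {
  tpl <- make_class_templates(4, 4, 0)
  mz <- seq(3000, 15000, by = 4)
  nz <- noise_model(baseline_amplitude = 2, baseline_decay = 1 / 4000,
                    additive_noise_sd = 1.5, intensity_jitter_cv = 0,
                    dropout_prob = 0)
  set.seed(99)
  reps <- t(replicate(1000, simulate_pixel(tpl$HP, nz, mz)$intensity))
  # closed-form mean of max(0, mu + eps), eps ~ N(0, sd): the independent
  # oracle for the Monte-Carlo mean
  mu <- simulate_pixel(tpl$HP, noiseless_noise(), mz)$intensity +
    2 * exp(-(mz - 3000) / 4000)
  sdv <- 1.5
  expected <- mu * pnorm(mu / sdv) + sdv * dnorm(mu / sdv)
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  check <- c(1, 500, 1500, 2500, length(mz))
  expect_true(all(abs(colMeans(reps)[check] - expected[check]) <=
                    3 * se[check] + 1e-12))
})

test_that("nodule composition is conserved within rounding", {
  cfg <- noiseless_config()
  tpl <- make_class_templates(cfg$rng_seed, cfg$n_peaks_per_class, 0)
  nod <- simulate_nodule("malignant", c(HP = 0.62, PTC = 0.38), cfg, tpl,
                         rng_seed = 5, cellularity = "optimal")
  n_inf <- sum(nod$coords$pixel_class != "background")
  expect_gte(n_inf / nrow(nod$coords), 0.7)
  tab <- table(nod$coords$pixel_class)
  expect_lte(abs(tab[["HP"]] - 0.62 * n_inf), 1)
  expect_lte(abs(tab[["PTC"]] - 0.38 * n_inf), 1)

  pure <- simulate_nodule("benign", c(HP = 1), cfg, tpl, rng_seed = 6,
                          cellularity = "good")
  expect_false("PTC" %in% pure$coords$pixel_class)

  opt <- simulate_nodule("malignant", c(PTC = 1), cfg, tpl, rng_seed = 7,
                         cellularity = "optimal")
  inf <- opt$coords$pixel_class != "background"
  expect_gte(mean(inf), 0.7)
  expect_true(all(opt$coords$pixel_class[inf] == "PTC"))

  expect_error(simulate_nodule("benign", c(HP = 0.7, PTC = 0.2), cfg, tpl, 1),
               "sum to 1")
})

test_that("ROIs are nonoverlapping single-class blocks of informative pixels", {
  cfg <- small_config(pixels_per_nodule = 400, rois_per_nodule = 5)
  co <- simulate_cohort(cfg)
  nod <- get_nodule(co, "TR008") # a PTC training nodule
  expect_gt(nrow(nod$rois), 0)
  expect_false(any(duplicated(paste(nod$rois$x, nod$rois$y))))
  key <- paste(nod$coords$x, nod$coords$y)
  for (rid in unique(nod$rois$roi_id)) {
    rr <- nod$rois[nod$rois$roi_id == rid, ]
    expect_gte(nrow(rr), cfg$roi_min_pixels)
    px_class <- nod$coords$pixel_class[match(paste(rr$x, rr$y), key)]
    expect_true(all(px_class == rr$label[1]))
  }
  # the dominant class of a malignant nodule is represented among ROI labels
  expect_true("PTC" %in% nod$rois$label)
})

test_that("default cohort design reproduces the study margins", {
  co <- simulate_cohort(cohort_config())
  m <- co$manifest
  tr <- m[m$set == "training", ]
  expect_equal(nrow(tr), 70)
  expect_equal(unname(table(tr$subtype)[c("HP", "HT", "PTC")]),
               c(40L, 10L, 20L), ignore_attr = TRUE)
  expect_true(all(tr$cellularity %in% c("good", "optimal")))

  va <- m[m$set == "validation", ]
  expect_equal(nrow(va), 170)
  expect_equal(unname(c(table(va$cytology)[c("TIR2", "TIR3", "TIR4", "TIR5")])),
               c(33L, 77L, 19L, 41L), ignore_attr = TRUE)
  expect_equal(sum(va$truth == "malignant"), 65)
  # 29 borderline histologies; 72 adequate-cellularity samples 17/23/9/23
  expect_equal(sum(va$subtype %in% c("FA", "NIFTP", "WDT-UMP")), 29)
  adq <- va[va$cellularity %in% c("good", "optimal"), ]
  expect_equal(nrow(adq), 72)
  expect_equal(unname(c(table(adq$cytology)[c("TIR2", "TIR3", "TIR4", "TIR5")])),
               c(17L, 23L, 9L, 23L), ignore_attr = TRUE)
})

test_that("cohorts are reproducible: byte-identical manifests, identical pixels", {
  cfg <- small_config(rng_seed = 42)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_manifest(simulate_cohort(cfg)$manifest, f1)
  write_manifest(simulate_cohort(cfg)$manifest, f2)
  expect_identical(readLines(f1), readLines(f2))

  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(get_nodule(co1, "TR002"), get_nodule(co2, "TR002"))
})

test_that("configured per-class ROI totals are honored", {
  cfg <- cohort_config(pixels_per_nodule = 1600,
                       shared_peak_fraction = 0,
                       noise = noiseless_noise())
  co <- simulate_cohort(cfg, roi_targets = c(HP = 381, HT = 50, PTC = 174))
  tr_ids <- co$manifest$sample_id[co$manifest$set == "training"]
  labels <- unlist(lapply(tr_ids, function(sid) {
    r <- get_nodule(co, sid)$rois
    r$label[!duplicated(r$roi_id)] # one label per ROI, not per pixel
  }))
  expect_equal(length(labels), 605)
  expect_equal(unname(table(labels)[c("HP", "HT", "PTC")]),
               c(381L, 50L, 174L), ignore_attr = TRUE)
})

test_that("raising additive noise never improves mean pixel accuracy", {
  accs <- sapply(1:10, function(r) {
    sapply(c(1, 12), function(sdv) {
      cfg <- cohort_config(
        n_hp_train = 2, n_ht_train = 2, n_ptc_train = 2,
        validation_cytology = c(TIR2 = 0, TIR3 = 0, TIR4 = 0, TIR5 = 0),
        pixels_per_nodule = 100, rois_per_nodule = 3, roi_min_pixels = 8,
        mz_step = 2, shared_peak_fraction = 0,
        noise = noise_model(additive_noise_sd = sdv), rng_seed = r)
      co <- simulate_cohort(cfg)
      # stringent SNR threshold so feature bins stay clean in the noisy arm
      pc <- preprocess_config(peak_snr_threshold = 8)
      pd <- thyromsi:::extract_peaks(co, pc)
      bins <- bin_peaks(thyromsi:::roi_peak_tibble(pd),
                        pc$bin_tolerance)$feature_mzs
      mats <- thyromsi:::unit_matrices(pd, bins, pc)
      model <- fit_lasso_multinomial(mats$roi, mats$roi$meta$label,
                                     cv_folds = 3, rng_seed = r)
      calls <- classify_units(model, mats$pixel)
      inf <- calls$pixel_class %in% c("HP", "HT", "PTC")
      mean(calls$class_call[inf] == calls$pixel_class[inf])
    })
  })
  expect_lte(mean(accs[2, ]), mean(accs[1, ]) + 1e-9)
})
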