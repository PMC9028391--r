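test_that("confusion counts partition the samples", {
  cc <- confusion(c("malignant", "malignant", "benign"),
                  c("malignant", "benign", "benign"))
  expect_equal(as.list(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 1L, fn = 0L))
  all_ok <- confusion(c("benign", "malignant"), c("benign", "malignant"))
  expect_equal(all_ok$fp + all_ok$fn, 0)
  expect_error(confusion(character(), character()), "nonempty")
  expect_error(confusion("malignant", "tumor"), "unknown truth")
  # inadequate predictions are excluded and counted
  ci <- confusion(c("inadequate", "malignant"), c("benign", "malignant"))
  expect_equal(attr(ci, "n_inadequate"), 1L)
  expect_equal(ci$tp, 1L)
})

test_that("zero-denominator metrics are undefined, not zero", {
  m <- diagnostic_metrics(c(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_equal(m$estimate[m$metric == "specificity"], 1)
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_true(is.na(m$estimate[m$metric == "ppv"]))
  expect_error(diagnostic_metrics(c(tp = 0, fp = 0, tn = 0, fn = 0)),
               "positive total")
})

test_that("accuracy identity holds for every report", {
  set.seed(8)
  for (i in 1:50) {
    cts <- c(tp = rpois(1, 20), fp = rpois(1, 10), tn = rpois(1, 30),
             fn = rpois(1, 15))
    if (sum(cts) == 0) cts["tp"] <- 1
    m <- diagnostic_metrics(cts)
    P <- cts[["tp"]] + cts[["fn"]]
    N <- cts[["tn"]] + cts[["fp"]]
    sens <- m$estimate[m$metric == "sensitivity"]
    spec <- m$estimate[m$metric == "specificity"]
    acc <- m$estimate[m$metric == "accuracy"]
    if (P > 0 && N > 0) {
      expect_equal(acc, (sens * P + spec * N) / (P + N), tolerance = 1e-12)
    }
    ok <- !is.na(m$estimate)
    expect_true(all(m$ci_low[ok] <= m$estimate[ok] + 1e-12))
    expect_true(all(m$ci_high[ok] >= m$estimate[ok] - 1e-12))
  }
})

test_that("exact intervals invert the binomial tail tests", {
  expect_equal(exact_binomial_ci(0, 10)[["low"]], 0)
  expect_equal(exact_binomial_ci(10, 10)[["high"]], 1)
  expect_error(exact_binomial_ci(5, 4), "k <= n")

  # brute-force inversion on a fine grid of p, plus the stats::binom.test
  # implementation as a second, independent reference
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:80, 1)
    k <- sample(0:n, 1)
    ci <- exact_binomial_ci(k, n)
    bt <- stats::binom.test(k, n)$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-9)
    p <- seq(0, 1, by = 1e-5)
    lo_grid <- if (k == 0) 0 else min(p[pbinom(k - 1, n, p) < 0.975])
    hi_grid <- if (k == n) 1 else max(p[pbinom(k, n, p) > 0.025])
    expect_lt(abs(ci[["low"]] - lo_grid), 2e-5)
    expect_lt(abs(ci[["high"]] - hi_grid), 2e-5)
  }
})

test_that("interval coverage is conservative and matches the exact rate", {
  n <- 30
  p_true <- 0.7
  k <- 0:n
  lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
  exact_cov <- sum(dbinom(k, n, p_true) * (lo <= p_true & p_true <= hi))

  set.seed(2022)
  draws <- rbinom(2000, n, p_true)
  covered <- vapply(draws, function(kk) {
    ci <- exact_binomial_ci(kk, n)
    ci[["low"]] <= p_true && p_true <= ci[["high"]]
  }, TRUE)
  cov_hat <- mean(covered)
  expect_gte(cov_hat, 0.95)
  se <- sqrt(exact_cov * (1 - exact_cov) / 2000)
  expect_lt(abs(cov_hat - exact_cov), 3 * se + 1e-9)
})

test_that("subgroup filters reproduce the designed cohort margins", {
  m <- design_manifest(cohort_config())
  va <- m[m$set == "validation", ]
  diag <- tibble::tibble(sample_id = va$sample_id,
                         call_pixel = "benign", call_roi = "benign",
                         call_overall_avg = "benign")
  rep <- subgroup_report(diag, va,
                         subgroups = c("all", "borderline_excluded",
                                       "adequate",
                                       "borderline_excluded+adequate"))
  n_of <- function(sg) unique(rep$n_samples[rep$subgroup == sg])
  expect_equal(n_of("all"), 170L)
  expect_equal(n_of("borderline_excluded"), 141L)
  expect_equal(n_of("adequate"), 72L)
  expect_lte(n_of("borderline_excluded+adequate"), 72L)
  expect_error(subgroup_report(diag, va, subgroups = "everyone"),
               "unknown subgroup")

  empty <- subgroup_report(diag[0, ], va[0, ])
  expect_true(all(empty$n_samples == 0))
})

test_that("three-level tables conserve counts and support triage agreement", {
  m <- tibble::tibble(sample_id = sprintf("S%02d", 1:9),
                      truth = rep(c("benign", "malignant"), c(5, 4)),
                      subtype = c(rep("HP", 4), "FA", rep("PTC", 3), "MTC"))
  d <- tibble::tibble(
    sample_id = m$sample_id,
    call_three_level = c("benign", "benign", "gray", "malignant", "benign",
                         "malignant", "malignant", "gray", "malignant"))
  tab <- three_level_table(d, m)
  expect_equal(sum(tab$total), 9)
  expect_equal(sum(tab$benign + tab$gray + tab$malignant), 9)
  expect_equal(triage_agreement(tab, "malignant", count_gray = TRUE), 1)
  expect_equal(triage_agreement(tab, "malignant", count_gray = FALSE), 3 / 4)

  d2 <- d
  d2$call_three_level <- "gray"
  tab2 <- three_level_table(d2, m)
  expect_equal(sum(tab2$gray), 9)
  expect_equal(sum(tab2$benign) + sum(tab2$malignant), 0)
})

test_that("PCA separates duplicated groups and keeps variance bookkeeping", {
  set.seed(41)
  base <- rnorm(20)
  x <- rbind(matrix(rep(base, 5), 5, byrow = TRUE),
             matrix(rep(base + 3, 5), 5, byrow = TRUE))
  x <- x + matrix(rnorm(200, sd = 0.01), 10)
  pc <- pca_explore(x)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-9)
  expect_gt(abs(mean(pc$scores$PC1[1:5]) - mean(pc$scores$PC1[6:10])), 1)

  expect_error(pca_explore(x[1, , drop = FALSE]), "2 samples")
  xz <- cbind(x, 0)
  expect_warning(pca_explore(xz), "zero-variance")
})

test_that("the eigenvalue spectrum is rotation-invariant (unscaled PCA)", {
  set.seed(9)
  x <- matrix(rnorm(30 * 6), 30, 6)
  rot <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  p1 <- pca_explore(x, scale = FALSE)
  p2 <- pca_explore(x %*% rot, scale = FALSE)
  expect_equal(p1$sdev, p2$sdev, tolerance = 1e-9)
})

test_that("benign nodules cluster more tightly than malignant ones", {
  cfg <- cohort_config(
    n_hp_train = 6, n_ht_train = 0, n_ptc_train = 6,
    validation_cytology = c(TIR2 = 0, TIR3 = 0, TIR4 = 0, TIR5 = 0),
    pixels_per_nodule = 120, rois_per_nodule = 2, roi_min_pixels = 8,
    mz_step = 2, shared_peak_fraction = 0, rng_seed = 77)
  co <- simulate_cohort(cfg)
  # heterogeneous malignant group: tumor fraction varies nodule to nodule
  pc0 <- preprocess_config()
  fracs <- seq(0.3, 1, length.out = 6)
  pd <- list()
  for (i in 1:6) {
    nb <- simulate_nodule("benign", c(HP = 1), cfg, co$templates, 1000 + i,
                          "optimal", sprintf("B%02d", i))
    nm <- simulate_nodule("malignant", c(HP = 1 - fracs[i], PTC = fracs[i]),
                          cfg, co$templates, 2000 + i, "optimal",
                          sprintf("M%02d", i))
    pd[[sprintf("B%02d", i)]] <- thyromsi:::process_nodule(nb, pc0)
    pd[[sprintf("M%02d", i)]] <- thyromsi:::process_nodule(nm, pc0)
  }
  class(pd) <- "msi_peakdata"
  rp <- thyromsi:::roi_peak_tibble(pd)
  bins <- bin_peaks(rp, pc0$bin_tolerance)$feature_mzs
  mats <- thyromsi:::unit_matrices(pd, bins, pc0)
  pc <- pca_explore(mats$overall$values)
  sc <- as.matrix(pc$scores[, c("PC1", "PC2")])
  grp <- substr(mats$overall$unit_ids, 1, 1)
  within <- function(g) mean(dist(sc[grp == g, ]))
  expect_lt(within("B"), within("M"))
})
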