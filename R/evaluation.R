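# Diagnostic performance: confusion counts, sensitivity/specificity/PPV/NPV/
# accuracy with Clopper-Pearson exact 95% confidence intervals, subgroup
# reports, the three-level triage cross-tabulation, and exploratory PCA.

#' Confusion counts (malignant = positive)
#'
#' @param pred,truth Aligned character vectors with values
#'   `benign`/`malignant` (`inadequate` predictions are dropped with their
#'   truth labels and counted in the `n_inadequate` attribute).
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (!length(pred) || length(pred) != length(truth)) {
    abort("`pred` and `truth` must be nonempty and of equal length")
  }
  bad <- setdiff(unique(truth), c("benign", "malignant"))
  if (length(bad)) abort(paste0("unknown truth label: ", paste(bad, collapse = ", ")))
  keep <- pred %in% c("benign", "malignant")
  n_inad <- sum(!keep)
  pred <- pred[keep]
  truth <- truth[keep]
  out <- tibble::tibble(
    tp = sum(pred == "malignant" & truth == "malignant"),
    fp = sum(pred == "malignant" & truth == "benign"),
    tn = sum(pred == "benign" & truth == "benign"),
    fn = sum(pred == "benign" & truth == "malignant")
  )
  attr(out, "n_inadequate") <- n_inad
  out
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Beta-quantile formulation of the interval obtained by inverting the two
#' binomial tail tests; the lower bound is exactly 0 when `k = 0` and the
#' upper bound exactly 1 when `k = n`.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (!is.numeric(k) || !is.numeric(n) || n < 1 || k < 0 || k > n ||
      k != floor(k) || n != floor(n)) {
    abort("need integer 0 <= k <= n, n >= 1")
  }
  a <- 1 - level
  low <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Diagnostic performance metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy, each with its exact binomial 95% confidence interval. Metrics
#' with a zero denominator are reported as undefined (`NA`), never as 0.
#'
#' @param counts One-row tibble or named vector with `tp`, `fp`, `tn`, `fn`.
#' @param conf_level Confidence level for the intervals.
#' @return Tibble with one row per metric: `metric`, `k`, `n`, `estimate`
#'   (proportion), `ci_low`, `ci_high`.
#' @export
diagnostic_metrics <- function(counts, conf_level = 0.95) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn < 1) {
    abort("counts must be nonnegative with a positive total")
  }
  one <- function(metric, k, n) {
    if (n == 0) {
      return(tibble::tibble(metric = metric, k = NA_integer_, n = 0L,
                            estimate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
    }
    ci <- exact_binomial_ci(k, n, conf_level)
    tibble::tibble(metric = metric, k = as.integer(k), n = as.integer(n),
                   estimate = k / n, ci_low = ci[["low"]],
                   ci_high = ci[["high"]])
  }
  dplyr::bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("ppv", tp, tp + fp),
    one("npv", tn, tn + fn),
    one("accuracy", tp + tn, tp + fp + tn + fn)
  )
}

subgroup_filters <- function() {
  list(
    all = function(m) rep(TRUE, nrow(m)),
    borderline_excluded = function(m) !(m$subtype %in% c("NIFTP", "FA", "WDT-UMP")),
    adequate = function(m) m$cellularity %in% c("good", "optimal")
  )
}

apply_subgroup <- function(manifest, spec) {
  parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
  flt <- subgroup_filters()
  bad <- setdiff(parts, names(flt))
  if (length(bad)) abort(paste0("unknown subgroup: ", paste(bad, collapse = ", ")))
  keep <- rep(TRUE, nrow(manifest))
  for (p in parts) keep <- keep & flt[[p]](manifest)
  keep
}

#' Diagnostic performance by subgroup and aggregation approach
#'
#' Subgroups: `all`; `borderline_excluded` (drops NIFTP, FA and WDT-UMP
#' histologies); `adequate` (keeps good/optimal cellularity). Filters can be
#' composed with `+`, e.g. `"borderline_excluded+adequate"`.
#'
#' @param diagnoses An `msi_diagnosis` tibble (or any tibble with
#'   `sample_id` and `call_*` columns).
#' @param manifest Cohort manifest with `sample_id`, `truth`, `subtype`,
#'   `cellularity`.
#' @param subgroups Character vector of subgroup specifications.
#' @param approaches Which call columns to evaluate.
#' @return Tibble: one row per subgroup x approach x metric, with counts and
#'   exact CIs; empty subgroups are flagged with `n_samples = 0`.
#' @export
subgroup_report <- function(diagnoses, manifest,
                            subgroups = c("all", "borderline_excluded",
                                          "adequate"),
                            approaches = c(pixel = "call_pixel",
                                           roi = "call_roi",
                                           overall_avg = "call_overall_avg")) {
  d <- dplyr::inner_join(tibble::as_tibble(diagnoses),
                         manifest[, c("sample_id", "truth", "subtype",
                                      "cellularity")],
                         by = "sample_id")
  out <- list()
  for (sg in subgroups) {
    keep <- apply_subgroup(d, sg)
    dd <- d[keep, ]
    if (!nrow(dd)) {
      out[[length(out) + 1]] <- tibble::tibble(
        subgroup = sg, approach = names(approaches), n_samples = 0L,
        metric = NA_character_, k = NA_integer_, n = NA_integer_,
        estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      next
    }
    for (ap in names(approaches)) {
      cc <- confusion(dd[[approaches[[ap]]]], dd$truth)
      met <- diagnostic_metrics(cc)
      met$subgroup <- sg
      met$approach <- ap
      met$n_samples <- nrow(dd) - attr(cc, "n_inadequate")
      out[[length(out) + 1]] <- met
    }
  }
  dplyr::bind_rows(out)[, c("subgroup", "approach", "n_samples", "metric",
                            "k", "n", "estimate", "ci_low", "ci_high")]
}

#' Three-level triage cross-tabulation by histology subtype
#'
#' @param diagnoses An `msi_diagnosis` tibble with `call_three_level`.
#' @param manifest Manifest with `sample_id`, `truth`, `subtype`.
#' @return Tibble: one row per truth x subtype with columns `benign`,
#'   `gray`, `malignant`, `total`.
#' @export
three_level_table <- function(diagnoses, manifest) {
  d <- dplyr::inner_join(tibble::as_tibble(diagnoses),
                         manifest[, c("sample_id", "truth", "subtype")],
                         by = "sample_id")
  d <- d[d$call_three_level %in% c("benign", "gray", "malignant"), ]
  tab <- dplyr::count(d, .data$truth, .data$subtype, .data$call_three_level)
  out <- tidyr::pivot_wider(tab, names_from = "call_three_level",
                            values_from = "n", values_fill = 0L)
  for (col in c("benign", "gray", "malignant")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out$total <- out$benign + out$gray + out$malignant
  dplyr::arrange(out[, c("truth", "subtype", "benign", "gray", "malignant",
                         "total")], .data$truth, .data$subtype)
}

#' Agreement rate of the three-level triage with a truth class
#'
#' Fraction of samples of the given truth class whose triage call agrees
#' (benign call for benign truth, malignant call for malignant truth);
#' gray-zone calls can be counted as agreement, mirroring a
#' follow-up-resolves-gray reading.
#'
#' @param tab Output of [three_level_table()] (or a tibble with `truth` and
#'   `benign`/`gray`/`malignant` count columns).
#' @param truth_class `"benign"` or `"malignant"`.
#' @param count_gray Whether gray-zone calls count as agreement.
#' @return Agreement as a proportion in `[0, 1]`.
#' @export
triage_agreement <- function(tab, truth_class = c("malignant", "benign"),
                             count_gray = TRUE) {
  truth_class <- match.arg(truth_class)
  t2 <- tab[tab$truth == truth_class, ]
  if (!nrow(t2)) abort("no rows with the requested truth class")
  agree <- sum(t2[[truth_class]]) + if (count_gray) sum(t2$gray) else 0L
  agree / sum(t2$benign + t2$gray + t2$malignant)
}

#' Exploratory PCA of average spectra
#'
#' Principal component analysis on centered (and by default unit-variance
#' scaled) data; zero-variance columns are dropped with a warning. Scores
#' are returned for every component with a positive eigenvalue and the
#' explained-variance fractions over those components sum to 1.
#'
#' @param x Numeric matrix or data frame, rows = samples (e.g. nodule
#'   average spectra or feature rows).
#' @param scale Scale columns to unit variance (default `TRUE`).
#' @return An `msi_pca` object with `scores` tibble, `explained_variance`,
#'   `loadings` and `sdev`.
#' @export
pca_explore <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 samples")
  if (ncol(x) < 2) abort("PCA needs at least 2 features")
  v <- apply(x, 2, stats::var)
  if (scale && any(v == 0)) {
    warn(sprintf("dropping %d zero-variance column(s)", sum(v == 0)))
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale)
  lam <- pc$sdev^2
  pos <- lam > max(lam) * 1e-12
  scores <- tibble::as_tibble(pc$x[, pos, drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(unit_id = rownames(x) %||% as.character(seq_len(nrow(x)))),
    scores)
  structure(list(scores = scores,
                 explained_variance = lam[pos] / sum(lam[pos]),
                 loadings = pc$rotation[, pos, drop = FALSE],
                 sdev = pc$sdev[pos]),
            class = "msi_pca")
}

#' @export
print.msi_pca <- function(x, ...) {
  cat("<msi_pca> ", nrow(x$scores), " samples, ",
      length(x$explained_variance), " components; PC1 ",
      pct_round(100 * x$explained_variance[1]), "% of variance\n", sep = "")
  invisible(x)
}

#' PCA scores in long-friendly form
#' @param x An `msi_pca` object.
#' @param ... Unused.
#' @export
tidy.msi_pca <- function(x, ...) x$scores

#' One-row PCA summary
#' @param x An `msi_pca` object.
#' @param ... Unused.
#' @export
glance.msi_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$explained_variance),
                 var_pc1 = x$explained_variance[1],
                 var_pc2 = if (length(x$explained_variance) > 1)
                   x$explained_variance[2] else NA_real_)
}
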