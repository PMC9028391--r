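# Three-class (HP / HT / PTC) L1-penalized multinomial classifier fitted on
# ROI-average feature matrices. The penalty is chosen by stratified k-fold
# cross-validation maximizing classification accuracy; ties go to the larger
# (sparser) penalty. glmnet solves the penalized paths; penalty selection,
# fold construction and the reporting scale are handled here.

#' Fit the L1-penalized multinomial classifier
#'
#' Features are standardized to unit variance internally; coefficients are
#' kept on the standardized scale together with the standardization
#' parameters (and their raw-scale equivalents for prediction). The lasso
#' penalty is selected on glmnet's log-spaced grid by maximal mean
#' cross-validated accuracy over stratified, seeded folds; on ties the larger
#' penalty (sparser model) wins.
#'
#' @param x An `msi_features` object (ROI level) or numeric matrix.
#' @param labels Class label per row (`HP`, `HT`, `PTC`); all three classes
#'   must be present.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param rng_seed Seed for the stratified fold assignment.
#' @param lambda Optional fixed penalty; when supplied, cross-validated
#'   selection is skipped and the model is extracted at this penalty
#'   (useful for inspecting lightly regularized fits).
#' @return An `msi_lasso` model object.
#' @export
fit_lasso_multinomial <- function(x, labels, cv_folds = 5, rng_seed = 1L,
                                  lambda = NULL) {
  feature_mzs <- NULL
  if (inherits(x, "msi_features")) {
    feature_mzs <- x$feature_mzs
    x <- x$values
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) abort("`labels` must match rows of `x`")
  bad <- setdiff(unique(labels), msi_classes())
  if (length(bad)) abort(paste0("unknown labels: ", paste(bad, collapse = ", ")))
  missing_cl <- setdiff(msi_classes(), unique(labels))
  if (length(missing_cl)) {
    abort(paste0("class absent from training: ", paste(missing_cl, collapse = ", ")))
  }
  if (nrow(x) < cv_folds) abort("fewer rows than folds")

  sds <- apply(x, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warn(sprintf("dropping %d constant feature(s)", sum(const)))
    x <- x[, !const, drop = FALSE]
    if (!is.null(feature_mzs)) feature_mzs <- feature_mzs[!const]
    sds <- sds[!const]
  }
  if (!ncol(x)) abort("no non-constant features left")
  centers <- colMeans(x)
  z <- scale(x, center = centers, scale = sds)

  y <- factor(labels, levels = msi_classes())
  full <- glmnet::glmnet(z, y, family = "multinomial", alpha = 1,
                         standardize = FALSE)
  lambda_fixed <- lambda
  lambda <- full$lambda

  if (!is.null(lambda_fixed)) {
    cv_accuracy <- rep(NA_real_, length(lambda))
    best <- NA_real_
    foldid <- integer(0)
    lambda_best <- lambda_fixed
  } else {
  set.seed(rng_seed)
  foldid <- integer(nrow(z))
  for (cl in msi_classes()) {
    i <- which(labels == cl)
    foldid[i] <- sample(rep_len(seq_len(cv_folds), length(i)))
  }

  correct <- matrix(0, cv_folds, length(lambda))
  for (f in seq_len(cv_folds)) {
    tr <- foldid != f
    fit_f <- glmnet::glmnet(z[tr, , drop = FALSE], y[tr],
                            family = "multinomial", alpha = 1,
                            standardize = FALSE, lambda = lambda)
    pr <- predict(fit_f, z[!tr, , drop = FALSE], type = "class",
                  s = lambda, exact = FALSE)
    correct[f, ] <- colSums(pr == as.character(y[!tr]))
  }
  cv_accuracy <- colSums(correct) / nrow(z)
  best <- max(cv_accuracy)
  tie <- cv_accuracy >= best - 1e-12
  # At the head of the path the fold fits can carry active features while
  # the full fit is still null, making the CV estimate and the full model
  # disagree. Resolve accuracy ties by requiring the full fit to attain the
  # maximal training accuracy within the tie set, then take the largest
  # (sparsest) lambda.
  pr_train <- predict(full, z, type = "class", s = lambda, exact = FALSE)
  train_acc <- colMeans(pr_train == labels)
  best_tr <- max(train_acc[tie])
  lambda_best <- max(lambda[tie & train_acc >= best_tr - 1e-12])
  }

  cf <- glmnet::coef.glmnet(full, s = lambda_best)
  a0_std <- vapply(cf, function(m) m[1, 1], 0)
  beta_std <- t(vapply(cf, function(m) as.numeric(m[-1, 1]),
                       numeric(ncol(z))))
  rownames(beta_std) <- msi_classes()
  beta_raw <- sweep(beta_std, 2, sds, `/`)
  a0_raw <- a0_std - as.numeric(beta_std %*% (centers / sds))

  structure(list(
    classes = msi_classes(),
    feature_mzs = feature_mzs %||% seq_len(ncol(x)),
    center = centers, scale = sds,
    beta_std = beta_std, a0_std = a0_std,
    beta_raw = beta_raw, a0_raw = setNames(a0_raw, msi_classes()),
    lambda = lambda_best, lambda_path = lambda,
    n_active_path = as.integer(full$df),
    cv_accuracy = cv_accuracy,
    cv_accuracy_best = best,
    cv_folds = cv_folds, foldid = foldid,
    rng_seed = rng_seed, n_obs = nrow(z),
    selected_features = (feature_mzs %||% seq_len(ncol(x)))[
      colSums(abs(beta_std)) > 0]
  ), class = "msi_lasso")
}

#' @export
print.msi_lasso <- function(x, ...) {
  cat("<msi_lasso> 3-class L1 multinomial model\n",
      "  features: ", length(x$feature_mzs), " (",
      length(x$selected_features), " selected)\n",
      "  lambda: ", signif(x$lambda, 4),
      "  CV accuracy: ", pct_round(100 * x$cv_accuracy_best), "%\n", sep = "")
  invisible(x)
}

#' Coefficients of a fitted classifier, one row per class and feature
#' @param x An `msi_lasso` model.
#' @param ... Unused.
#' @return Tibble with standardized- and raw-scale coefficients.
#' @export
tidy.msi_lasso <- function(x, ...) {
  p <- length(x$feature_mzs)
  tibble::tibble(
    class = rep(x$classes, each = p),
    feature_mz = rep(x$feature_mzs, times = 3),
    estimate_std = as.vector(t(x$beta_std)),
    estimate_raw = as.vector(t(x$beta_raw)),
    center = rep(x$center, times = 3),
    scale = rep(x$scale, times = 3)
  )
}

#' One-row model summary
#' @param x An `msi_lasso` model.
#' @param ... Unused.
#' @export
glance.msi_lasso <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, n_features = length(x$feature_mzs),
    n_selected = length(x$selected_features),
    cv_accuracy = x$cv_accuracy_best, cv_folds = x$cv_folds,
    n_obs = x$n_obs
  )
}

#' Persist a fitted classifier as JSON
#'
#' Stores classes, the feature m/z axis, dense standardized coefficients,
#' the standardization parameters, the selected penalty, and the fold
#' assignment, so a model can be re-applied without refitting.
#'
#' @param model An `msi_lasso` model.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    classes = model$classes, feature_mzs = model$feature_mzs,
    center = unname(model$center), scale = unname(model$scale),
    beta_std = unname(model$beta_std), a0_std = unname(model$a0_std),
    lambda = model$lambda, cv_folds = model$cv_folds,
    cv_accuracy_best = model$cv_accuracy_best,
    rng_seed = model$rng_seed, foldid = model$foldid, n_obs = model$n_obs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [write_model()]
#' @param path JSON path.
#' @return An `msi_lasso` model.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta_std <- matrix(p$beta_std, nrow = 3,
                     dimnames = list(p$classes, NULL))
  scale <- as.numeric(p$scale)
  center <- as.numeric(p$center)
  beta_raw <- sweep(beta_std, 2, scale, `/`)
  a0_raw <- p$a0_std - as.numeric(beta_std %*% (center / scale))
  structure(list(
    classes = p$classes, feature_mzs = as.numeric(p$feature_mzs),
    center = center, scale = scale,
    beta_std = beta_std, a0_std = setNames(p$a0_std, p$classes),
    beta_raw = beta_raw, a0_raw = setNames(a0_raw, p$classes),
    lambda = p$lambda, lambda_path = numeric(), n_active_path = integer(),
    cv_accuracy = numeric(), cv_accuracy_best = p$cv_accuracy_best,
    cv_folds = p$cv_folds, foldid = p$foldid, rng_seed = p$rng_seed,
    n_obs = p$n_obs,
    selected_features = as.numeric(p$feature_mzs)[colSums(abs(beta_std)) > 0]
  ), class = "msi_lasso")
}

# map a feature matrix onto the model's feature axis (missing features -> 0)
map_features <- function(model, x, tolerance = 0.002) {
  if (inherits(x, "msi_features")) {
    if (length(x$feature_mzs) == length(model$feature_mzs) &&
        all(x$feature_mzs == model$feature_mzs)) {
      return(list(values = x$values, ids = x$unit_ids, meta = x$meta))
    }
    tgt <- model$feature_mzs
    out <- matrix(0, nrow(x$values), length(tgt),
                  dimnames = list(x$unit_ids, NULL))
    hit <- 0L
    for (j in seq_along(tgt)) {
      d <- abs(x$feature_mzs - tgt[j])
      k <- which.min(d)
      if (length(k) && d[k] <= tolerance * tgt[j]) {
        out[, j] <- x$values[, k]
        hit <- hit + 1L
      }
    }
    if (hit == 0L) abort("no overlapping features between model and matrix")
    return(list(values = out, ids = x$unit_ids, meta = x$meta))
  }
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_mzs)) {
    abort("matrix columns do not match model features")
  }
  list(values = x, ids = rownames(x) %||% as.character(seq_len(nrow(x))),
       meta = NULL)
}

#' Predict class membership probabilities
#'
#' Softmax of the per-class linear scores of the fitted multinomial model;
#' every row sums to one. An all-zero feature row yields the softmax of the
#' model intercepts alone.
#'
#' @param model An `msi_lasso` model.
#' @param x An `msi_features` object or matrix with matching feature axis.
#' @return Tibble with `unit_id`, `p_hp`, `p_ht`, `p_ptc` (plus any unit
#'   metadata carried by `x`).
#' @export
predict_probs <- function(model, x) {
  m <- map_features(model, x)
  eta <- sweep(m$values %*% t(model$beta_raw), 2, model$a0_raw, `+`)
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  pr <- e / rowSums(e)
  out <- tibble::tibble(unit_id = m$ids, p_hp = pr[, "HP"],
                        p_ht = pr[, "HT"], p_ptc = pr[, "PTC"])
  if (!is.null(m$meta)) {
    out <- dplyr::left_join(out, m$meta, by = "unit_id")
  }
  out
}

#' Hard class calls by maximum probability
#'
#' Argmax over the three class probabilities with a deterministic tie-break
#' (PTC over HT over HP on exact ties, so a tie never silently favors a
#' benign class).
#'
#' @inheritParams predict_probs
#' @return Tibble: `unit_id`, the three probabilities, `class_call`.
#' @export
classify_units <- function(model, x) {
  pr <- predict_probs(model, x)
  pr$class_call <- call_from_probs(pr$p_hp, pr$p_ht, pr$p_ptc)
  pr
}

#' Class call from three membership probabilities
#'
#' Argmax with a fixed PTC > HT > HP priority on exact ties, so a tie never
#' silently favors a benign class.
#'
#' @param p_hp,p_ht,p_ptc Probability vectors (rows sum to 1).
#' @return Character vector of class calls.
#' @examples
#' call_from_probs(1 / 3, 1 / 3, 1 / 3) # "PTC" by tie priority
#' @export
call_from_probs <- function(p_hp, p_ht, p_ptc) {
  m <- cbind(PTC = p_ptc, HT = p_ht, HP = p_hp)
  colnames(m)[max.col(m, ties.method = "first")]
}
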