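#' Preprocessing configuration
#'
#' Fixes the spectral preprocessing chain applied to every pixel: trim to the
#' acquisition m/z range, Savitzky-Golay smoothing, SNIP baseline subtraction
#' (clamped at zero) and TIC normalization. Defaults follow common MALDI
#' linear-mode practice.
#'
#' @param smoothing_half_window Savitzky-Golay half-window in grid points
#'   (quadratic polynomial; window = 2h + 1). Default 10.
#' @param baseline_iterations SNIP clipping iterations. Default 100.
#' @param normalization `"TIC"` (intensities sum to 1) or `"none"`.
#' @param peak_snr_threshold Minimal signal-to-noise ratio for peak picking;
#'   noise is the median absolute deviation of the processed spectrum.
#' @param bin_tolerance Relative m/z tolerance used to merge peaks across
#'   units into shared features (default 0.002, i.e. 10 Da at 5000 Da).
#' @param mz_range Acquisition window in Da.
#' @return An `msi_preprocess_config` list.
#' @export
preprocess_config <- function(smoothing_half_window = 10,
                              baseline_iterations = 100,
                              normalization = c("TIC", "none"),
                              peak_snr_threshold = 3,
                              bin_tolerance = 0.002,
                              mz_range = c(3000, 15000)) {
  normalization <- match.arg(normalization)
  stop_if_not_scalar_count(smoothing_half_window, "smoothing_half_window")
  if (smoothing_half_window < 1) abort("`smoothing_half_window` must be >= 1")
  stop_if_not_scalar_count(baseline_iterations, "baseline_iterations")
  if (!is.numeric(peak_snr_threshold) || peak_snr_threshold <= 0) {
    abort("`peak_snr_threshold` must be positive")
  }
  if (!is.numeric(bin_tolerance) || bin_tolerance <= 0 || bin_tolerance >= 0.1) {
    abort("`bin_tolerance` must be in (0, 0.1)")
  }
  structure(list(smoothing_half_window = as.integer(smoothing_half_window),
                 baseline_iterations = as.integer(baseline_iterations),
                 normalization = normalization,
                 peak_snr_threshold = peak_snr_threshold,
                 bin_tolerance = bin_tolerance,
                 mz_range = mz_range),
            class = "msi_preprocess_config")
}

# center row of the least-squares quadratic smoothing filter
sg_coefficients <- function(half_window, order = 2) {
  k <- -half_window:half_window
  A <- outer(k, 0:order, `^`)
  H <- A %*% solve(crossprod(A)) %*% t(A)
  H[half_window + 1, ]
}

# row-wise preprocessing of a pixels-by-grid intensity matrix (already
# trimmed); returns processed matrix, per-row TIC and retained flag
preprocess_matrix <- function(X, cfg) {
  res <- cpp_preprocess(X, sg_coefficients(cfg$smoothing_half_window),
                        cfg$baseline_iterations,
                        cfg$normalization == "TIC")
  res$retained <- res$tic > 0
  res
}

trim_grid <- function(mz, cfg) which(mz >= cfg$mz_range[1] & mz <= cfg$mz_range[2])

#' Preprocess one pixel spectrum
#'
#' Chain: trim to the configured m/z range, Savitzky-Golay smooth, subtract
#' a SNIP baseline (clamped at zero), TIC-normalize. A spectrum that is empty
#' after trimming, or whose total ion current is zero after baseline
#' subtraction, is flagged empty (attribute `"empty"`) and excluded from
#' downstream analyses.
#'
#' @param spec Tibble with sorted `mz` and nonnegative `intensity`.
#' @param cfg An [preprocess_config()].
#' @return Tibble `mz`, `intensity` with attribute `"empty"`.
#' @export
preprocess_spectrum <- function(spec, cfg = preprocess_config()) {
  if (is.unsorted(spec$mz, strictly = TRUE)) abort("spectrum m/z must be strictly increasing")
  keep <- trim_grid(spec$mz, cfg)
  if (!length(keep)) {
    out <- tibble::tibble(mz = numeric(), intensity = numeric())
    attr(out, "empty") <- TRUE
    return(out)
  }
  res <- preprocess_matrix(matrix(spec$intensity[keep], nrow = 1), cfg)
  out <- tibble::tibble(mz = spec$mz[keep], intensity = res$intensity[1, ])
  attr(out, "empty") <- !res$retained[1]
  out
}

#' Pick peaks from a preprocessed spectrum
#'
#' Local intensity maxima whose signal-to-noise ratio reaches the configured
#' threshold; the noise level is the median absolute deviation of the whole
#' processed spectrum.
#'
#' @inheritParams preprocess_spectrum
#' @return Tibble with columns `mz`, `intensity` (possibly zero rows).
#' @export
pick_peaks <- function(spec, cfg = preprocess_config()) {
  if (!nrow(spec)) return(tibble::tibble(mz = numeric(), intensity = numeric()))
  pk <- cpp_pick_peaks(matrix(spec$intensity, nrow = 1), cfg$peak_snr_threshold)[[1]]
  tibble::tibble(mz = spec$mz[pk$index], intensity = pk$intensity)
}

#' Pointwise mean of preprocessed spectra on a common grid
#'
#' @param spectra List of spectra tibbles (`mz`, `intensity`) sharing one
#'   m/z grid.
#' @return Tibble `mz`, `intensity` (the arithmetic mean).
#' @export
average_spectrum <- function(spectra) {
  if (!length(spectra)) abort("cannot average an empty set of spectra")
  mz <- spectra[[1]]$mz
  for (s in spectra) {
    if (!identical(length(s$mz), length(mz)) || any(s$mz != mz)) {
      abort("spectra must share a common m/z grid")
    }
  }
  M <- do.call(rbind, lapply(spectra, function(s) s$intensity))
  tibble::tibble(mz = mz, intensity = colMeans(M))
}
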