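#' Round percentages the way clinical performance tables print them
#'
#' Half-up rounding to one decimal, applied after an intermediate half-up
#' rounding to two decimals. The two-stage scheme matches the convention of
#' common clinical reporting workflows (values such as 69.048 print as 69.1,
#' not 69.0, because the hundredths digit is rounded first).
#'
#' @param x Numeric vector of percentages (e.g. 67.647).
#' @param digits Number of decimals in the final value (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' pct_round(100 * 87 / 126) # 69.1
#' pct_round(100 * 28 / 65)  # 43.1
#' @export
pct_round <- function(x, digits = 1) {
  half_up <- function(z, d) floor(z * 10^d + 0.5 + 1e-9) / 10^d
  half_up(half_up(x, digits + 1), digits)
}

# largest-remainder apportionment of n units across proportions `w`
alloc_largest_remainder <- function(w, n) {
  if (n == 0L) return(integer(length(w)))
  if (sum(w) <= 0) abort("proportions must have a positive sum")
  q <- w / sum(w) * n
  k <- floor(q)
  r <- n - sum(k)
  if (r > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(r)]] <- k[ord[seq_len(r)]] + 1
  }
  as.integer(k)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single nonnegative integer", name))
  }
}

msi_classes <- function() c("HP", "HT", "PTC")

benign_classes <- function() c("HP", "HT")

#' Map a three-class call to the binary benign/malignant scale
#'
#' HP (hyperplastic) and HT (Hashimoto thyroiditis) are benign phenotypes;
#' PTC (papillary thyroid carcinoma) is malignant.
#'
#' @param class_call Character vector with values in `HP`, `HT`, `PTC`.
#' @return Character vector with values `benign` or `malignant`.
#' @export
binary_call <- function(class_call) {
  bad <- setdiff(unique(class_call), msi_classes())
  if (length(bad)) abort(paste0("unknown class call: ", paste(bad, collapse = ", ")))
  ifelse(class_call == "PTC", "malignant", "benign")
}
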