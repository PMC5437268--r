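#' Tumour LOD model for candidate substitutions
#'
#' The tumour LOD score is the log10 ratio of the likelihood that a candidate
#' variant is a real tumour event to the likelihood that the supporting reads
#' arose from sequencing error alone. Reads are modelled as independent draws
#' from a two-component mixture: a read at a site with true variant allele
#' fraction `f` shows the alternate base with probability
#' `f * (1 - e) + (1 - f) * e / 3` and the reference base with probability
#' `(1 - f) * (1 - e) + f * e / 3`, where `e` is the per-base substitution
#' error rate (a specific wrong base is read with probability `e / 3`).
#' The variant hypothesis is evaluated at the maximum-likelihood allele
#' fraction `alt_count / depth`; the error hypothesis at `f = 0`.
#'
#' A single uniform error rate stands in for per-read base qualities: the
#' downstream filtering statistic operates on the within-sample distribution
#' of LOD scores, not on their absolute calibration, so only structural
#' parity with quality-aware callers is needed (or claimed).
#'
#' @name lod_model
#' @keywords internal
NULL

.check_error_rate <- function(error_rate) {
  if (!is.numeric(error_rate) || any(!is.finite(error_rate)) ||
      any(error_rate <= 0) || any(error_rate >= 0.5)) {
    stop("'error_rate' must lie strictly between 0 and 0.5", call. = FALSE)
  }
  invisible(error_rate)
}

.check_counts <- function(alt_count, depth) {
  if (any(depth < 1)) stop("'depth' must be >= 1", call. = FALSE)
  if (any(alt_count < 0) || any(alt_count > depth)) {
    stop("'alt_count' must lie in [0, depth]", call. = FALSE)
  }
  invisible(NULL)
}

#' Maximum-likelihood allele fraction
#'
#' Under the two-component read model the MLE of the variant allele fraction
#' is simply the observed fraction of alternate reads.
#'
#' @param alt_count Integer vector, alternate-supporting read counts.
#' @param depth Integer vector, total read depth (>= 1).
#' @return Numeric vector of allele fractions in `[0, 1]`.
#' @examples
#' allele_fraction_mle(50, 20000)  # 0.0025, a 0.25% allele fraction
#' @export
allele_fraction_mle <- function(alt_count, depth) {
  .check_counts(alt_count, depth)
  alt_count / depth
}

#' Tumour LOD score from read counts
#'
#' Computes `sum over reads of log10 P(read | f = f_hat) / P(read | f = 0)`
#' with `f_hat = alt_count / depth`, grouped in closed form as
#' `alt * log10(p_alt(f_hat) / p_alt(0)) + ref * log10(p_ref(f_hat) / p_ref(0))`.
#' The score is exactly 0 when `alt_count = 0` and strictly increasing in
#' `alt_count` at fixed depth and error rate.
#'
#' @inheritParams allele_fraction_mle
#' @param error_rate Per-base substitution error probability in (0, 0.5).
#'   A specific wrong base is read with probability `error_rate / 3`.
#' @return Numeric vector of LOD scores (log10 units).
#' @examples
#' tumour_lod(50, 20000, error_rate = 5e-4)  # a 0.25% AF variant at 20,000x
#' tumour_lod(0, 20000)                      # exactly 0
#' @export
tumour_lod <- function(alt_count, depth, error_rate = 1e-3) {
  .check_error_rate(error_rate)
  .check_counts(alt_count, depth)
  f <- alt_count / depth
  e3 <- error_rate / 3
  p_alt_f <- f * (1 - error_rate) + (1 - f) * e3
  p_ref_f <- (1 - f) * (1 - error_rate) + f * e3
  p_alt_0 <- e3
  p_ref_0 <- 1 - error_rate
  lod <- alt_count * log10(p_alt_f / p_alt_0) +
    (depth - alt_count) * log10(p_ref_f / p_ref_0)
  # f = 0 makes both hypotheses identical; force the exact zero
  lod[alt_count == 0] <- 0
  lod
}

#' Smallest detectable alternate-read count at a given LOD threshold
#'
#' Returns the minimal `alt_count` whose [tumour_lod()] reaches `lod_min` at
#' the given depth and error rate, using the monotonicity of the score in
#' `alt_count` (binary search). `NA_integer_` signals that no count up to
#' `depth` attains the threshold.
#'
#' @param depth Integer scalar, read depth (>= 1).
#' @param error_rate Per-base substitution error probability in (0, 0.5).
#' @param lod_min Non-negative LOD threshold.
#' @return Integer scalar (or `NA_integer_` if not attainable).
#' @examples
#' detection_floor(20000, error_rate = 5e-4, lod_min = 30)
#' @export
detection_floor <- function(depth, error_rate = 1e-3, lod_min = 0) {
  stopifnot(length(depth) == 1L, depth >= 1, length(lod_min) == 1L,
            lod_min >= 0)
  .check_error_rate(error_rate)
  if (tumour_lod(0L, depth, error_rate) >= lod_min) return(0L)
  if (tumour_lod(depth, depth, error_rate) < lod_min) return(NA_integer_)
  lo <- 0L  # below threshold
  hi <- as.integer(depth)  # at or above threshold
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (tumour_lod(mid, depth, error_rate) >= lod_min) hi <- mid else lo <- mid
  }
  hi
}
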