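#' Per-sample modified Z-score filtering of tumour LOD scores
#'
#' Absolute tumour LOD scores drift between samples and sequencing batches,
#' so candidate calls are filtered on a *modified Z-score*: the distance of a
#' call's LOD from the sample median, divided by the sample MAD. Both
#' statistics are computed over the calls the upstream caller kept
#' (judgement `KEEP`), and the MAD is the raw median absolute deviation —
#' no 1.4826 consistency constant and no 0.6745 modified-Z constant — because
#' the detection threshold is calibrated on exactly this statistic.
#'
#' The stepwise filter assigns every call to the first step that removes it:
#'
#' 1. `REMOVED_JUDGEMENT` — upstream `REJECT` (and non-analysable flagged
#'    rows, which never reach the statistic);
#' 2. `REMOVED_Z` — modified Z-score below the threshold;
#' 3. `REMOVED_GERMLINE` — population allele frequency above the germline
#'    cutoff (strict inequality);
#' 4. `SOMATIC_KEPT` — everything that survives all three steps.
#'
#' Because the Z-score is invariant under adding a constant to all LODs of a
#' sample, dispositions are unchanged by additive batch effects.
#'
#' @name filtering
#' @keywords internal
NULL

.DISPOSITIONS <- c("SOMATIC_KEPT", "REMOVED_JUDGEMENT", "REMOVED_Z",
                   "REMOVED_GERMLINE")

#' Filtering configuration
#'
#' @param z_threshold Modified Z-score acceptance threshold; a call passes
#'   when its Z-score is `>= z_threshold` (inclusive). Default 20, the
#'   ROC-calibrated value for the 5-gene panel.
#' @param pop_af_cutoff Germline population-frequency cutoff; calls with
#'   `pop_af > pop_af_cutoff` (strict) are removed as likely germline.
#'   Default 0.001 (0.1%).
#' @param mad_floor Substitute scale for degenerate samples whose MAD is 0.
#' @return A list of class `lbseq_filter_config`.
#' @export
filter_config <- function(z_threshold = 20, pop_af_cutoff = 0.001,
                          mad_floor = 1e-6) {
  stopifnot(z_threshold > 0, pop_af_cutoff >= 0, pop_af_cutoff < 1,
            mad_floor > 0)
  structure(list(z_threshold = z_threshold, pop_af_cutoff = pop_af_cutoff,
                 mad_floor = mad_floor),
            class = "lbseq_filter_config")
}

#' Robust location and scale of a sample's LOD scores
#'
#' Median and raw MAD (median of absolute deviations from the median,
#' without consistency constants) of the tumour LOD scores over the calls
#' kept by the upstream caller. A sample whose MAD is exactly 0 is flagged
#' degenerate and `mad_floor` is substituted so that cohort runs stay
#' robust.
#'
#' @param callset An `lbseq_calls` object with at least one unflagged
#'   `KEEP` call.
#' @param mad_floor Scale substitute for MAD = 0 samples.
#' @return List with elements `median`, `mad`, `degenerate`.
#' @examples
#' cs <- sample_callset("S01", data.frame(
#'   contig = "chr1", position = 1:3, ref_allele = "A", alt_allele = "T",
#'   t_ref_count = 99L, t_alt_count = 1L, tumour_f = 0.01,
#'   t_lod = c(1, 2, 3), judgement = "KEEP"))
#' lod_location_scale(cs)  # median 2, MAD 1
#' @export
lod_location_scale <- function(callset, mad_floor = 1e-6) {
  stopifnot(inherits(callset, "lbseq_calls"))
  pool <- callset$calls$t_lod[callset$calls$judgement == "KEEP" &
                                !callset$calls$flagged]
  if (!length(pool)) {
    stop(errorCondition(
      paste0("sample ", callset$sample_id, " has no KEEP calls; ",
             "no location/scale statistics can be computed"),
      class = c("lbseq_empty_sample", "error", "condition")))
  }
  med <- stats::median(pool)
  mad_raw <- stats::median(abs(pool - med))
  degenerate <- mad_raw == 0
  list(median = med, mad = if (degenerate) mad_floor else mad_raw,
       degenerate = degenerate)
}

#' Modified Z-scores for every call of a sample
#'
#' `z = (t_lod - median) / mad`, computed for all calls (including rejected
#' ones, for reporting) against the KEEP-pool statistics.
#'
#' @param callset An `lbseq_calls` object.
#' @param stats Statistics from [lod_location_scale()]; computed on the fly
#'   when omitted.
#' @return Numeric vector aligned with `callset$calls` rows.
#' @export
modified_z_scores <- function(callset, stats = lod_location_scale(callset)) {
  stopifnot(inherits(callset, "lbseq_calls"))
  (callset$calls$t_lod - stats$median) / stats$mad
}

#' Germline population-frequency filter
#'
#' Partitions calls on the population allele frequency annotation: a call is
#' removed as likely germline iff `pop_af` is present and strictly exceeds
#' the cutoff; unannotated calls are kept.
#'
#' @param calls Data frame of calls (the `calls` element of an
#'   `lbseq_calls` object).
#' @param cutoff Population-frequency cutoff (default 0.001, i.e. 0.1%).
#' @return List with data frames `kept` and `removed`, and the logical mask
#'   `removed_mask`.
#' @export
germline_popaf_filter <- function(calls, cutoff = 0.001) {
  removed_mask <- !is.na(calls$pop_af) & calls$pop_af > cutoff
  list(kept = calls[!removed_mask, , drop = FALSE],
       removed = calls[removed_mask, , drop = FALSE],
       removed_mask = removed_mask)
}

#' Run the stepwise LB-Seq filter on one sample
#'
#' Applies the three filtering steps (judgement, modified Z-score, germline
#' population frequency) in order, attributing each call to the first step
#' that removes it, and reports the per-sample statistics alongside the
#' LOD threshold implied by the Z-score threshold
#' (`median + z_threshold * mad`).
#'
#' A sample with no `KEEP` calls yields a report with all calls
#' `REMOVED_JUDGEMENT` and `NA` statistics rather than an error.
#'
#' @param callset An `lbseq_calls` object.
#' @param config A [filter_config()].
#' @return An object of class `lbseq_filter`: the input calls with `z` and
#'   `disposition` columns, per-category `counts`, and the sample statistics.
#' @examples
#' cs <- sample_callset("S01", data.frame(
#'   contig = "chr1", position = 1:5, ref_allele = "A", alt_allele = "T",
#'   t_ref_count = 100L, t_alt_count = 5L, tumour_f = 5 / 105,
#'   t_lod = c(2, 3, 4, 5, 100), judgement = "KEEP",
#'   pop_af = c(NA, NA, NA, 0.3, NA)))
#' run_lbseq_filter(cs)
#' @export
run_lbseq_filter <- function(callset, config = filter_config()) {
  stopifnot(inherits(callset, "lbseq_calls"),
            inherits(config, "lbseq_filter_config"))
  calls <- callset$calls
  n <- nrow(calls)
  stats <- tryCatch(lod_location_scale(callset, config$mad_floor),
                    lbseq_empty_sample = function(e) NULL)
  if (is.null(stats)) {
    calls$z <- rep(NA_real_, n)
    calls$disposition <- rep("REMOVED_JUDGEMENT", n)
    stats <- list(median = NA_real_, mad = NA_real_, degenerate = FALSE)
    lod_threshold <- NA_real_
  } else {
    calls$z <- modified_z_scores(callset, stats)
    removed_judgement <- calls$judgement != "KEEP" | calls$flagged
    removed_z <- !removed_judgement & calls$z < config$z_threshold
    germline <- germline_popaf_filter(calls, config$pop_af_cutoff)$removed_mask
    removed_germline <- !removed_judgement & !removed_z & germline
    disposition <- rep("SOMATIC_KEPT", n)
    disposition[removed_germline] <- "REMOVED_GERMLINE"
    disposition[removed_z] <- "REMOVED_Z"
    disposition[removed_judgement] <- "REMOVED_JUDGEMENT"
    calls$disposition <- disposition
    lod_threshold <- stats$median + config$z_threshold * stats$mad
  }
  counts <- vapply(.DISPOSITIONS, function(d) sum(calls$disposition == d),
                   integer(1))
  structure(list(sample_id = callset$sample_id,
                 patient_id = callset$patient_id,
                 config = config,
                 lod_median = stats$median,
                 lod_mad = stats$mad,
                 mad_degenerate = stats$degenerate,
                 lod_threshold = lod_threshold,
                 calls = calls,
                 counts = counts),
            class = "lbseq_filter")
}

#' @export
print.lbseq_filter <- function(x, ...) {
  cat("LB-Seq filter report:", x$sample_id, "\n")
  cat(sprintf("  LOD median %.4g, MAD %.4g%s -> LOD threshold %.4g (Z >= %g)\n",
              x$lod_median, x$lod_mad,
              if (isTRUE(x$mad_degenerate)) " [degenerate, floored]" else "",
              x$lod_threshold, x$config$z_threshold))
  for (d in .DISPOSITIONS) cat(sprintf("  %-18s %d\n", d, x$counts[[d]]))
  invisible(x)
}

#' @export
summary.lbseq_filter <- function(object, ...) {
  kept <- object$calls[object$calls$disposition == "SOMATIC_KEPT", ,
                       drop = FALSE]
  print(object)
  if (nrow(kept)) {
    cat("somatic calls kept:\n")
    print(kept[, c("contig", "position", "ref_allele", "alt_allele",
                   "tumour_f", "t_lod", "z", "gene")], row.names = FALSE)
  }
  invisible(object)
}

#' Strip chart of a sample's LOD scores by disposition
#'
#' @param x An `lbseq_filter` report.
#' @param ... Passed to [graphics::stripchart()].
#' @return Invisibly, `x`.
#' @export
plot.lbseq_filter <- function(x, ...) {
  calls <- x$calls
  calls$disposition <- factor(calls$disposition, levels = .DISPOSITIONS)
  graphics::stripchart(t_lod ~ disposition, data = calls, vertical = TRUE,
                       method = "jitter", pch = 16,
                       col = c("firebrick", "grey40", "grey60", "steelblue"),
                       ylab = "tumour LOD score", main = x$sample_id, ...)
  if (!is.na(x$lod_threshold)) {
    graphics::abline(h = x$lod_threshold, lty = 2)
  }
  invisible(x)
}
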