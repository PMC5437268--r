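#' Threshold training and cohort evaluation against bone-marrow truth
#'
#' The Z-score threshold is trained on a cohort with matched bone-marrow
#' (BM) truth by sweeping candidate thresholds, measuring pooled sensitivity
#' (truth mutations detected) and specificity (non-truth candidates
#' removed), and selecting the threshold that maximizes Youden's J. Cohort
#' performance at a fixed configuration is summarized as concordance
#' (detected / truth, reported as a rounded percent) plus candidate-level
#' specificity. Truth matching is by exact locus (contig, position, ref,
#' alt); the specificity denominator is the pooled set of non-truth `KEEP`
#' candidates, the only denominator computable from call tables.
#'
#' @name training_eval
#' @keywords internal
NULL

.cohort_eval_frame <- function(cohort, truth) {
  stopifnot(length(cohort) > 0L)
  pieces <- lapply(cohort, function(cs) {
    stopifnot(inherits(cs, "lbseq_calls"))
    calls <- cs$calls
    keep <- calls$judgement == "KEEP" & !calls$flagged
    calls <- calls[keep, , drop = FALSE]
    stats <- tryCatch(lod_location_scale(cs),
                      lbseq_empty_sample = function(e) NULL)
    z <- if (is.null(stats)) numeric(0) else
      (calls$t_lod - stats$median) / stats$mad
    data.frame(sample_id = rep(cs$sample_id, nrow(calls)),
               patient_id = rep(cs$patient_id, nrow(calls)),
               key = locus_key(calls), z = z,
               germline = !is.na(calls$pop_af),
               pop_af = calls$pop_af,
               stringsAsFactors = FALSE)
  })
  frame <- do.call(rbind, pieces)
  rownames(frame) <- NULL
  frame
}

#' Sweep the modified Z-score threshold over a ROC grid
#'
#' For each threshold, the full stepwise filter is applied to every sample
#' of the cohort and pooled sensitivity/specificity are computed against
#' the truth set:
#' * sensitivity — fraction of truth mutations whose locus is
#'   `SOMATIC_KEPT` in at least one sample of the matching patient;
#' * specificity — fraction of pooled non-truth `KEEP` candidates that the
#'   filter removed.
#'
#' The per-sample Z-scores do not depend on the threshold, so the sweep
#' computes them once and applies each threshold vectorized; this is
#' equivalent to rerunning [run_lbseq_filter()] per threshold (asserted in
#' the test suite by direct recount).
#'
#' @param cohort List of `lbseq_calls` objects.
#' @param truth An `lbseq_truth` data frame.
#' @param thresholds Sorted numeric grid of candidate Z thresholds
#'   (default integers 1–100).
#' @param config Base [filter_config()] supplying the germline cutoff.
#' @return Data frame of class `lbseq_roc` with columns `z_threshold`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @export
sweep_roc <- function(cohort, truth, thresholds = 1:100,
                      config = filter_config()) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  stopifnot(inherits(truth, "lbseq_truth"), length(thresholds) > 0L,
            !is.unsorted(thresholds))
  frame <- .cohort_eval_frame(cohort, truth)
  patients <- vapply(cohort, function(cs) cs$patient_id, character(1))
  truth <- truth[truth$patient_id %in% patients, , drop = FALSE]
  truth_key <- paste(truth$patient_id, locus_key(truth))
  frame_key <- paste(frame$patient_id, frame$key)
  is_truth <- frame_key %in% truth_key
  # a germline-annotated call above the cutoff can never be SOMATIC_KEPT
  germ_removed <- !is.na(frame$pop_af) & frame$pop_af > config$pop_af_cutoff
  # best achievable z per truth record among non-germline matching calls
  eligible <- is_truth & !germ_removed
  zmax <- vapply(truth_key, function(k) {
    zs <- frame$z[eligible & frame_key == k]
    if (length(zs)) max(zs) else -Inf
  }, numeric(1))
  nontruth_z <- frame$z[!is_truth & !germ_removed]
  n_nontruth <- sum(!is_truth)
  always_removed <- sum(!is_truth & germ_removed)

  points <- lapply(thresholds, function(t) {
    sens <- if (length(zmax)) mean(zmax >= t) else NA_real_
    fp <- sum(nontruth_z >= t)
    spec <- if (n_nontruth) (n_nontruth - fp) / n_nontruth else NA_real_
    data.frame(z_threshold = t, sensitivity = sens, specificity = spec)
  })
  roc <- do.call(rbind, points)
  roc$youden_j <- roc$sensitivity + roc$specificity - 1
  class(roc) <- c("lbseq_roc", "data.frame")
  roc
}

#' Select the operating threshold from a ROC sweep
#'
#' Maximizes Youden's J (`sensitivity + specificity - 1`); ties are broken
#' toward the smaller threshold, favouring sensitivity.
#'
#' @param roc An `lbseq_roc` data frame from [sweep_roc()].
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "lbseq_roc"), nrow(roc) > 0L)
  best <- roc$z_threshold[roc$youden_j == max(roc$youden_j)]
  min(best)
}

#' @export
plot.lbseq_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "b", pch = 16,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, max(1 - x$specificity, 0.05)), ylim = c(0, 1),
                 ...)
  best <- which(x$youden_j == max(x$youden_j))[1L]
  graphics::points(1 - x$specificity[best], x$sensitivity[best],
                   col = "firebrick", cex = 2)
  invisible(x)
}

#' Cohort concordance against a bone-marrow truth set
#'
#' Runs the stepwise filter on every sample and scores, per truth mutation,
#' whether its locus is `SOMATIC_KEPT` in any cfDNA sample of the matching
#' patient. Truth records for patients absent from the cohort are dropped;
#' cohort patients without truth records contribute to false-positive
#' accounting only (with a warning). Concordance is reported as a percent
#' rounded to the nearest integer.
#'
#' @param cohort List of `lbseq_calls` objects.
#' @param truth An `lbseq_truth` data frame.
#' @param config A [filter_config()].
#' @return Object of class `lbseq_concordance` with elements `n_truth`,
#'   `n_detected`, `concordance_pct`, `sensitivity_pct`, `fp_calls`,
#'   `n_nontruth`, `specificity_pct`.
#' @export
concordance <- function(cohort, truth, config = filter_config()) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  stopifnot(inherits(truth, "lbseq_truth"))
  patients <- vapply(cohort, function(cs) cs$patient_id, character(1))
  no_truth <- setdiff(patients, truth$patient_id)
  if (length(no_truth)) {
    warning("cohort patient(s) without truth records (FP accounting only): ",
            paste(unique(no_truth), collapse = ", "), call. = FALSE)
  }
  truth <- truth[truth$patient_id %in% patients, , drop = FALSE]
  truth_key <- paste(truth$patient_id, locus_key(truth))

  detected <- logical(nrow(truth))
  fp_list <- list()
  n_nontruth <- 0L
  n_fp <- 0L
  for (cs in cohort) {
    report <- run_lbseq_filter(cs, config)
    calls <- report$calls
    cand <- calls$judgement == "KEEP" & !calls$flagged
    cand_key <- paste(cs$patient_id, locus_key(calls))
    kept <- calls$disposition == "SOMATIC_KEPT"
    detected <- detected | (truth_key %in% cand_key[kept])
    nontruth <- cand & !(cand_key %in% truth_key)
    n_nontruth <- n_nontruth + sum(nontruth)
    fp <- nontruth & kept
    n_fp <- n_fp + sum(fp)
    if (any(fp)) {
      fp_list[[length(fp_list) + 1L]] <- cbind(
        data.frame(sample_id = cs$sample_id, patient_id = cs$patient_id,
                   stringsAsFactors = FALSE),
        calls[fp, c("contig", "position", "ref_allele", "alt_allele",
                    "tumour_f", "t_lod", "z"), drop = FALSE])
    }
  }
  fp_calls <- if (length(fp_list)) do.call(rbind, fp_list) else NULL
  n_truth <- nrow(truth)
  n_detected <- sum(detected)
  structure(list(
    n_truth = n_truth,
    n_detected = n_detected,
    concordance_pct = if (n_truth) as.integer(round(100 * n_detected / n_truth))
                      else NA_integer_,
    sensitivity_pct = if (n_truth) 100 * n_detected / n_truth else NA_real_,
    fp_calls = fp_calls,
    n_nontruth = n_nontruth,
    specificity_pct = if (n_nontruth) 100 * (n_nontruth - n_fp) / n_nontruth
                      else NA_real_),
    class = "lbseq_concordance")
}

#' @export
print.lbseq_concordance <- function(x, ...) {
  cat(sprintf("LB-Seq cohort concordance: %d/%d truth mutations detected (%d%%)\n",
              x$n_detected, x$n_truth, x$concordance_pct))
  cat(sprintf("  specificity: %.2f%% of %d non-truth candidates removed\n",
              x$specificity_pct, x$n_nontruth))
  nfp <- if (is.null(x$fp_calls)) 0L else nrow(x$fp_calls)
  cat(sprintf("  calls kept but absent from truth: %d\n", nfp))
  invisible(x)
}

#' Per-patient allele-fraction regression between cfDNA and bone marrow
#'
#' Ordinary least-squares fit (with intercept) of cfDNA allele fractions on
#' bone-marrow allele fractions for one patient. At least three mutation
#' pairs are required; with fewer pairs the strength of correlation is not
#' assessed.
#'
#' @param cf_af Numeric vector of cfDNA allele fractions.
#' @param bm_af Numeric vector of matched bone-marrow allele fractions.
#' @return List with `r_squared`, `slope`, `intercept`, `n`.
#' @examples
#' af_regression(c(0.02, 0.04, 0.08), c(0.01, 0.02, 0.04))  # exact line
#' @export
af_regression <- function(cf_af, bm_af) {
  if (length(cf_af) != length(bm_af)) stop("length mismatch", call. = FALSE)
  if (length(cf_af) < 3L) {
    stop("at least three (cfDNA, BM) allele-fraction pairs are required",
         call. = FALSE)
  }
  if (stats::var(bm_af) == 0) {
    stop("zero variance in bone-marrow allele fractions: regression undefined",
         call. = FALSE)
  }
  fit <- stats::lm(cf_af ~ bm_af)
  # for simple OLS with intercept, R^2 is the squared Pearson correlation
  # (avoids summary.lm's perfect-fit warning on noiseless input)
  list(r_squared = stats::cor(cf_af, bm_af)^2,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(cf_af))
}

#' Subclonal rank concordance between cfDNA and bone marrow
#'
#' Compares the ordering of mutation allele fractions in cfDNA and bone
#' marrow; identical orderings indicate that the relative subclonal
#' composition of the marrow is reflected in plasma. The statistic is
#' Kendall's tau; the verdict is `"concordant"` exactly when all pairwise
#' orderings agree (tau = 1).
#'
#' @param cf_af,bm_af Paired numeric vectors (length >= 2).
#' @return List with `tau`, `concordant`, `verdict`.
#' @examples
#' rank_concordance(c(0.24, 0.0072), c(0.47, 0.014))  # concordant
#' @export
rank_concordance <- function(cf_af, bm_af) {
  if (length(cf_af) != length(bm_af)) stop("length mismatch", call. = FALSE)
  if (length(cf_af) < 2L) stop("need at least two pairs", call. = FALSE)
  tau <- stats::cor(cf_af, bm_af, method = "kendall")
  concordant <- isTRUE(all.equal(tau, 1))
  list(tau = tau, concordant = concordant,
       verdict = if (concordant) "concordant" else "discordant")
}

#' Fragment-overlap phasing of two nearby variants
#'
#' For two variants close enough to be covered by single DNA fragments,
#' tallies per-fragment co-occurrence. Absence of any fragment carrying
#' both variants (while each variant has support on its own) indicates the
#' two mutations reside in distinct subclones.
#'
#' @param has_a,has_b Logical vectors, one element per fragment covering
#'   both positions: does the fragment carry variant A / variant B?
#' @return List with `shared_count`, `a_only`, `b_only`, `n_fragments` and
#'   `verdict` in `{"co-occurring", "mutually exclusive", "mixed"}`.
#' @examples
#' phase_overlap(rep(c(TRUE, FALSE), c(10, 10)),
#'               rep(c(FALSE, TRUE), c(10, 10)))  # mutually exclusive
#' @export
phase_overlap <- function(has_a, has_b) {
  if (length(has_a) != length(has_b)) stop("length mismatch", call. = FALSE)
  stopifnot(is.logical(has_a), is.logical(has_b))
  shared <- sum(has_a & has_b)
  a_only <- sum(has_a & !has_b)
  b_only <- sum(!has_a & has_b)
  verdict <- if (shared == 0L && a_only > 0L && b_only > 0L) {
    "mutually exclusive"
  } else if (shared > 0L && a_only == 0L && b_only == 0L) {
    "co-occurring"
  } else {
    "mixed"
  }
  list(shared_count = shared, a_only = a_only, b_only = b_only,
       n_fragments = length(has_a), verdict = verdict)
}
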