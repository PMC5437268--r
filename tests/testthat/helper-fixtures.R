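# Fixture builders shared across the suite. Everything is generated in
# code; no files ship with the package.

# Minimal consistent call table around a vector of LOD scores.
calls_from_lods <- function(lods, judgement = "KEEP", pop_af = NA_real_) {
  n <- length(lods)
  data.frame(contig = "chr1", position = seq_len(n) * 10L,
             ref_allele = "A", alt_allele = "T",
             t_ref_count = 990L, t_alt_count = 10L, tumour_f = 0.01,
             t_lod = lods, judgement = judgement, pop_af = pop_af,
             stringsAsFactors = FALSE)
}

callset_from_lods <- function(lods, sample_id = "S01", ...) {
  sample_callset(sample_id, calls_from_lods(lods, ...))
}

# Random valid callset for round-trip properties.
random_callset <- function(n, sample_id = "S01") {
  loci <- panel_loci(n)
  depth <- sample(500:30000, n, replace = TRUE)
  alt <- sapply(depth, function(d) sample.int(d, 1L))
  data.frame(loci[c("contig", "position", "ref_allele", "alt_allele")],
             t_ref_count = as.integer(depth - alt), t_alt_count = as.integer(alt),
             tumour_f = alt / depth,
             t_lod = stats::runif(n, -5, 500),
             judgement = sample(c("KEEP", "REJECT"), n, replace = TRUE,
                                prob = c(0.9, 0.1)),
             pop_af = ifelse(stats::runif(n) < 0.3,
                             stats::runif(n, 1e-5, 0.5), NA_real_),
             gene = loci$gene,
             protein_change = ifelse(stats::runif(n) < 0.2, "p.Q61K",
                                     NA_character_),
             stringsAsFactors = FALSE) |>
    sample_callset(sample_id = sample_id, calls = _)
}

# Cohort in which exactly `n_detected` of `n_truth` single-mutation
# patients carry a call passing the filter; each sample also carries a
# low-LOD background so the per-sample statistics are well defined.
eval_cohort <- function(n_truth, n_detected) {
  cohort <- vector("list", n_truth)
  truth <- vector("list", n_truth)
  for (i in seq_len(n_truth)) {
    pid <- sprintf("P%03d", i)
    bg <- calls_from_lods(seq(1, 3, length.out = 10))
    spike <- calls_from_lods(1000)
    spike$position <- 100000L + i
    calls <- if (i <= n_detected) rbind(bg, spike) else bg
    cohort[[i]] <- sample_callset(sprintf("S%03d", i), calls,
                                  patient_id = pid)
    truth[[i]] <- data.frame(patient_id = pid, contig = "chr1",
                             position = 100000L + i, ref_allele = "A",
                             alt_allele = "T", bm_af = 0.1,
                             stringsAsFactors = FALSE)
  }
  list(cohort = cohort, truth = as_truth(do.call(rbind, truth)))
}
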