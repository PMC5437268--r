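#' Synthetic call tables with the statistical structure of deep cfDNA panels
#'
#' The generator emulates per-sample candidate-call tables from ultra-deep
#' (~20,000x) hybrid-capture sequencing of a small exon panel:
#'
#' * *artefact* calls — background substitution noise; per-site depth is
#'   negative binomial, alternate counts are `Binomial(depth, e_site)` where
#'   `e_site` equals the per-base error rate except at a small Pareto-tailed
#'   minority of sites with inflated error (library damage / recurrent
#'   artefacts);
#' * *germline* calls — heterozygous or homozygous SNPs
#'   (`Binomial(depth, 0.5)` or `Binomial(depth, 1)`) carrying population
#'   allele frequencies drawn log-uniform above the 0.1% germline cutoff
#'   (an optional rare-germline fraction draws below the cutoff, emulating
#'   variants missing from population databases);
#' * *somatic* spikes — variants at specified allele fractions, matched in
#'   the bone-marrow truth set.
#'
#' Tumour LOD scores are computed from the simulated counts via
#' [tumour_lod()], then shifted by a per-batch additive offset — batch
#' effects are modelled as location shifts of the LOD distribution only.
#' All draws descend from a single seed; per-sample substreams are derived
#' by fixed offsets, so output is bit-reproducible.
#'
#' @name synthetic_cohort
#' @keywords internal
NULL

# Five-gene exon-panel windows used to place synthetic loci (hg19-like
# coordinates; only used as address space, never dereferenced).
.PANEL_GENES <- data.frame(
  gene = c("KRAS", "NRAS", "BRAF", "EGFR", "PIK3CA"),
  contig = c("chr12", "chr1", "chr7", "chr7", "chr3"),
  start = c(25358180L, 115247085L, 140419127L, 55086714L, 178866311L),
  width = c(45000L, 12000L, 190000L, 188000L, 91000L),
  stringsAsFactors = FALSE)

.BASES <- c("A", "C", "G", "T")

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: ~20,000x
#' mean depth, 5e-4 per-base error, 200 artefact and 30 germline sites per
#' sample, somatic allele fractions spanning 0.25–46%, and two sequencing
#' batches whose LOD distributions differ by an additive +15 shift.
#'
#' @param n_samples Number of plasma samples (one per patient).
#' @param n_somatic Total somatic truth variants spread over the cohort.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param depth_mean,depth_dispersion Negative-binomial depth model
#'   (`mu`, `size`).
#' @param error_rate Per-base substitution error probability.
#' @param n_artefact Artefact sites per sample.
#' @param artefact_tail_frac Fraction of artefact sites with inflated
#'   error.
#' @param artefact_tail_min,artefact_tail_shape Pareto(min, shape)
#'   multiplier applied to `error_rate` at inflated sites.
#' @param n_germline Germline SNP calls per sample.
#' @param rare_germline_frac Fraction of germline SNPs whose population
#'   frequency falls below the 0.1% cutoff (default 0: all filterable).
#' @param somatic_af_range Range of somatic cfDNA allele fractions
#'   (drawn log-uniform).
#' @param batch_lod_shifts Additive LOD offsets, one per batch; samples
#'   are assigned to batches round-robin.
#' @param bm_noise_cv Relative noise linking bone-marrow AF to cfDNA AF.
#' @param bm_scale_meanlog,bm_scale_sdlog Lognormal per-patient scaling of
#'   bone-marrow AF relative to cfDNA AF (plasma tumour-content dilution).
#' @return A list of class `lbseq_cohort_config`.
#' @export
cohort_config <- function(n_samples = 48L, n_somatic = 51L, seed = 1L,
                          depth_mean = 20000L, depth_dispersion = 100,
                          error_rate = 5e-4, n_artefact = 200L,
                          artefact_tail_frac = 0.02,
                          artefact_tail_min = 2, artefact_tail_shape = 3,
                          n_germline = 30L, rare_germline_frac = 0,
                          somatic_af_range = c(0.0025, 0.46),
                          batch_lod_shifts = c(0, 15),
                          bm_noise_cv = 0.05,
                          bm_scale_meanlog = log(2), bm_scale_sdlog = 0.4) {
  stopifnot(n_samples >= 0, n_somatic >= 0, depth_mean >= 1,
            depth_dispersion > 0, error_rate > 0, error_rate < 0.5,
            n_artefact >= 0, artefact_tail_frac >= 0, artefact_tail_frac <= 1,
            artefact_tail_min >= 1, artefact_tail_shape > 0,
            n_germline >= 0, rare_germline_frac >= 0, rare_germline_frac <= 1,
            length(somatic_af_range) == 2L,
            somatic_af_range[1] <= somatic_af_range[2],
            somatic_af_range[1] > 0, somatic_af_range[2] < 1,
            length(batch_lod_shifts) >= 1L, bm_noise_cv >= 0,
            length(seed) == 1L, is.finite(seed))
  structure(list(n_samples = as.integer(n_samples),
                 n_somatic = as.integer(n_somatic),
                 seed = as.integer(seed),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate,
                 n_artefact = as.integer(n_artefact),
                 artefact_tail_frac = artefact_tail_frac,
                 artefact_tail_min = artefact_tail_min,
                 artefact_tail_shape = artefact_tail_shape,
                 n_germline = as.integer(n_germline),
                 rare_germline_frac = rare_germline_frac,
                 somatic_af_range = somatic_af_range,
                 batch_lod_shifts = batch_lod_shifts,
                 bm_noise_cv = bm_noise_cv,
                 bm_scale_meanlog = bm_scale_meanlog,
                 bm_scale_sdlog = bm_scale_sdlog),
            class = "lbseq_cohort_config")
}

.sample_seed <- function(cfg, sample_index) {
  (abs(cfg$seed) + 1000003 * sample_index) %% 2147483647L
}

#' Random distinct loci on the synthetic five-gene panel
#'
#' Draws `n` distinct substitution loci across the panel's gene windows,
#' with gene labels and random ref/alt bases. Used to place artefact,
#' germline and somatic calls; exported so spike-in experiments can build
#' their own somatic tables. Uses the current RNG state.
#'
#' @param n Number of loci.
#' @return Data frame with columns `contig, position, ref_allele,
#'   alt_allele, gene`.
#' @export
panel_loci <- function(n) .random_loci(n)

# n distinct loci on the panel, with gene labels and a substitution
.random_loci <- function(n) {
  if (!n) {
    return(data.frame(contig = character(), position = integer(),
                      ref_allele = character(), alt_allele = character(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  g <- sample.int(nrow(.PANEL_GENES), n, replace = TRUE)
  pos <- .PANEL_GENES$start[g] +
    vapply(.PANEL_GENES$width[g], function(w) sample.int(w, 1L), integer(1))
  # resample clashes until loci are unique within the draw
  key <- paste(.PANEL_GENES$contig[g], pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- .PANEL_GENES$start[g[dup]] +
      vapply(.PANEL_GENES$width[g[dup]], function(w) sample.int(w, 1L),
             integer(1))
    key <- paste(.PANEL_GENES$contig[g], pos)
  }
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), character(1))
  data.frame(contig = .PANEL_GENES$contig[g], position = as.integer(pos),
             ref_allele = ref, alt_allele = unname(alt),
             gene = .PANEL_GENES$gene[g], stringsAsFactors = FALSE)
}

.build_calls <- function(loci, depth, alt, lod, pop_af, label, true_af) {
  data.frame(contig = loci$contig, position = loci$position,
             ref_allele = loci$ref_allele, alt_allele = loci$alt_allele,
             t_ref_count = as.integer(depth - alt),
             t_alt_count = as.integer(alt),
             tumour_f = alt / depth, t_lod = lod,
             judgement = "KEEP", pop_af = pop_af,
             gene = loci$gene, protein_change = NA_character_,
             flagged = FALSE, label = label, true_af = true_af,
             stringsAsFactors = FALSE)
}

#' Simulate one plasma sample's candidate-call table
#'
#' Draws artefact, germline and (optionally) somatic calls per the
#' configured read-count mechanism, computes LOD scores via
#' [tumour_lod()], and applies the sample's batch LOD shift. Sites whose
#' simulated alternate count is zero are not emitted (a caller only emits
#' candidates with alternate support); a somatic spike can therefore be
#' absent from the call table while present in the truth set.
#'
#' @param cfg A [cohort_config()].
#' @param sample_index 1-based sample index; determines the random
#'   substream and the batch assignment (round-robin over
#'   `batch_lod_shifts`).
#' @param somatic Optional data frame of somatic spikes with columns
#'   `contig, position, ref_allele, alt_allele, gene, af`; `NULL` gives a
#'   background-only sample.
#' @param sample_id,patient_id Identifiers (defaults derived from the
#'   index).
#' @return List with `callset` (an `lbseq_calls`) and `labels`, a data
#'   frame giving each emitted call's ground-truth label
#'   (`artefact`/`germline`/`somatic`) and generative allele fraction.
#' @export
simulate_sample <- function(cfg, sample_index = 1L, somatic = NULL,
                            sample_id = sprintf("S%03d", sample_index),
                            patient_id = sprintf("P%03d", sample_index)) {
  stopifnot(inherits(cfg, "lbseq_cohort_config"))
  set.seed(.sample_seed(cfg, sample_index))
  batch <- ((sample_index - 1L) %% length(cfg$batch_lod_shifts)) + 1L
  shift <- cfg$batch_lod_shifts[batch]

  draw_depth <- function(n) {
    pmax(1L, stats::rnbinom(n, mu = cfg$depth_mean,
                            size = cfg$depth_dispersion))
  }
  parts <- list()

  # artefact background
  n_a <- cfg$n_artefact
  if (n_a > 0L) {
    loci <- .random_loci(n_a)
    depth <- draw_depth(n_a)
    e_site <- rep(cfg$error_rate, n_a)
    tail <- stats::runif(n_a) < cfg$artefact_tail_frac
    mult <- cfg$artefact_tail_min /
      stats::runif(sum(tail))^(1 / cfg$artefact_tail_shape)
    e_site[tail] <- pmin(0.1, e_site[tail] * mult)
    alt <- stats::rbinom(n_a, depth, e_site)
    parts$artefact <- .build_calls(loci, depth, alt,
                                   tumour_lod(alt, depth, cfg$error_rate),
                                   NA_real_, "artefact", e_site)
  }

  # germline SNPs
  n_g <- cfg$n_germline
  if (n_g > 0L) {
    loci <- .random_loci(n_g)
    depth <- draw_depth(n_g)
    af <- ifelse(stats::runif(n_g) < 1 / 3, 1, 0.5)
    alt <- stats::rbinom(n_g, depth, af)
    rare <- stats::runif(n_g) < cfg$rare_germline_frac
    pop_af <- 10^stats::runif(n_g, log10(0.0011), log10(0.5))
    pop_af[rare] <- 10^stats::runif(sum(rare), log10(1e-5), log10(9.9e-4))
    parts$germline <- .build_calls(loci, depth, alt,
                                   tumour_lod(alt, depth, cfg$error_rate),
                                   pop_af, "germline", af)
  }

  # somatic spikes
  if (!is.null(somatic) && nrow(somatic)) {
    depth <- draw_depth(nrow(somatic))
    alt <- stats::rbinom(nrow(somatic), depth, somatic$af)
    parts$somatic <- .build_calls(somatic, depth, alt,
                                  tumour_lod(alt, depth, cfg$error_rate),
                                  NA_real_, "somatic", somatic$af)
  }

  calls <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(calls)) calls <- cbind(.empty_calls(),
                                     label = character(),
                                     true_af = numeric())
  calls <- calls[calls$t_alt_count > 0L, , drop = FALSE]
  calls$t_lod <- calls$t_lod + shift
  calls <- calls[order(calls$contig, calls$position), , drop = FALSE]
  labels <- data.frame(sample_id = rep(sample_id, nrow(calls)),
                       key = locus_key(calls), label = calls$label,
                       true_af = calls$true_af, stringsAsFactors = FALSE)
  calls$label <- NULL
  calls$true_af <- NULL
  cs <- sample_callset(sample_id, calls, patient_id = patient_id,
                       batch_id = sprintf("B%02d", batch))
  list(callset = cs, labels = labels)
}

#' Simulate a cohort with matched bone-marrow truth
#'
#' Distributes `n_somatic` somatic variants over the samples (one sample
#' per patient), draws their cfDNA allele fractions log-uniform over
#' `somatic_af_range`, and derives bone-marrow allele fractions as
#' `cfDNA AF x patient scaling x (1 + Normal(0, bm_noise_cv))`, clipped to
#' `[0, 1]` — producing the per-patient linear AF relationship the
#' regression analysis assumes. The truth set contains every somatic
#' variant, including any whose simulated alternate count happened to be
#' zero.
#'
#' @param cfg A [cohort_config()].
#' @return List with `cohort` (list of `lbseq_calls`), `truth`
#'   (`lbseq_truth`), and `labels` (row-bound per-sample label tables).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "lbseq_cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  if (!n) {
    return(list(cohort = list(),
                truth = as_truth(data.frame(patient_id = character(),
                                            contig = character(),
                                            position = integer(),
                                            ref_allele = character(),
                                            alt_allele = character(),
                                            bm_af = numeric(),
                                            source = character())),
                labels = NULL))
  }
  patient_ids <- sprintf("P%03d", seq_len(n))
  ns <- cfg$n_somatic
  owner <- if (ns) sort(sample.int(n, ns, replace = TRUE)) else integer(0)
  loci <- .random_loci(ns)
  af <- 10^stats::runif(ns, log10(cfg$somatic_af_range[1]),
                        log10(cfg$somatic_af_range[2]))
  scale_p <- stats::rlnorm(n, cfg$bm_scale_meanlog, cfg$bm_scale_sdlog)
  bm_af <- af * scale_p[owner] * (1 + stats::rnorm(ns, 0, cfg$bm_noise_cv))
  bm_af <- pmin(1, pmax(1e-6, bm_af))
  truth <- as_truth(cbind(data.frame(patient_id = patient_ids[owner],
                                     stringsAsFactors = FALSE),
                          loci[c("contig", "position", "ref_allele",
                                 "alt_allele")],
                          data.frame(bm_af = bm_af,
                                     source = "five_gene_panel",
                                     stringsAsFactors = FALSE)))
  somatic_all <- cbind(loci, af = af, owner = owner)
  cohort <- vector("list", n)
  label_list <- vector("list", n)
  for (i in seq_len(n)) {
    som <- somatic_all[somatic_all$owner == i, , drop = FALSE]
    sim <- simulate_sample(cfg, i, somatic = if (nrow(som)) som else NULL,
                           patient_id = patient_ids[i])
    cohort[[i]] <- sim$callset
    label_list[[i]] <- sim$labels
  }
  list(cohort = cohort, truth = truth,
       labels = do.call(rbind, c(label_list, list(make.row.names = FALSE))))
}

#' Simulate a training cohort with a guaranteed Z-score separation
#'
#' Generates a cohort as [simulate_cohort()], then adjusts each sample's
#' LOD scores so that, per sample, every artefact call's modified Z-score
#' lies below `separation[1]` and every somatic call's above
#' `separation[2]` — with anchor calls placed just inside each bound so
#' the separation is tight. Because the modified Z-score is invariant
#' under affine maps of the LOD vector, target Z configurations are
#' realized by iterative re-pinning against the evolving median/MAD; the
#' guarantee is verified internally after adjustment. Germline calls are
#' left unconstrained (the population-frequency step removes them at any
#' threshold).
#'
#' @param cfg A [cohort_config()]; use ~25 samples for a
#'   training-cohort-sized run.
#' @param separation Numeric pair `(artefact z ceiling, somatic z floor)`
#'   with `ceiling < floor`.
#' @return As [simulate_cohort()].
#' @export
simulate_training_set <- function(cfg, separation = c(19.5, 20.5)) {
  stopifnot(inherits(cfg, "lbseq_cohort_config"),
            length(separation) == 2L, separation[1] < separation[2])
  z_ceiling <- separation[1]
  z_floor <- separation[2]
  sim <- simulate_cohort(cfg)
  for (i in seq_along(sim$cohort)) {
    cs <- sim$cohort[[i]]
    n <- nrow(cs$calls)
    if (n < 3L) {
      stop("sample ", cs$sample_id, " has fewer than 3 calls; the ",
           "requested separation is not realizable", call. = FALSE)
    }
    lab <- sim$labels$label[sim$labels$sample_id == cs$sample_id]
    art <- which(lab == "artefact")
    som <- which(lab == "somatic")
    germ <- which(lab == "germline")
    art_anchor <- if (length(art)) art[1L] else integer(0)
    som_anchor <- if (length(som)) som[1L] else integer(0)

    t <- stats::rnorm(n)
    t[art] <- pmin(3, pmax(-3, t[art]))
    if (length(germ)) t[germ] <- stats::runif(length(germ), 3, 10)
    converged <- FALSE
    for (it in 1:200) {
      m <- stats::median(t)
      s <- stats::median(abs(t - m))
      if (s == 0) s <- 1e-6
      z <- (t - m) / s
      ok <- (!length(art) || all(z[art] < z_ceiling)) &&
        (!length(som) || all(z[som] > z_floor)) &&
        (!length(art_anchor) || z[art_anchor] >= z_ceiling - 0.45) &&
        (!length(som_anchor) || z[som_anchor] <= z_floor + 0.45)
      if (ok) { converged <- TRUE; break }
      if (length(art_anchor)) t[art_anchor] <- m + s * (z_ceiling - 0.2)
      if (length(som_anchor)) t[som_anchor] <- m + s * (z_floor + 0.2)
      bad_art <- setdiff(art[z[art] >= z_ceiling - 0.5], art_anchor)
      if (length(bad_art)) {
        t[bad_art] <- m + s * stats::runif(length(bad_art), 0,
                                           max(1, z_ceiling - 1))
      }
      bad_som <- setdiff(som[z[som] <= z_floor + 0.5], som_anchor)
      if (length(bad_som)) {
        t[bad_som] <- m + s * stats::runif(length(bad_som), z_floor + 1,
                                           z_floor + 15)
      }
    }
    if (!converged) {
      stop("failed to realize the requested z separation for sample ",
           cs$sample_id, call. = FALSE)
    }
    batch <- ((i - 1L) %% length(cfg$batch_lod_shifts)) + 1L
    cs$calls$t_lod <- cfg$batch_lod_shifts[batch] + 10 + 3 * t
    # internal verification of the guarantee on the final LOD vector
    zf <- modified_z_scores(cs)
    stopifnot(!length(art) || all(zf[art] < z_ceiling),
              !length(som) || all(zf[som] > z_floor))
    sim$cohort[[i]] <- cs
  }
  sim
}

#' Write a simulated cohort to disk
#'
#' Writes one call-stats TSV per sample, a `samples.tsv` manifest carrying
#' the sample-to-patient/batch mapping (the call-stats dialect itself has
#' no metadata columns), plus `truth.tsv` and `labels.tsv`.
#'
#' @param sim Result of [simulate_cohort()] or [simulate_training_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cs in sim$cohort) {
    write_callstats(cs, file.path(dir, paste0(cs$sample_id, ".callstats.tsv")))
  }
  manifest <- data.frame(
    sample_id = vapply(sim$cohort, function(cs) cs$sample_id, character(1)),
    patient_id = vapply(sim$cohort, function(cs) cs$patient_id, character(1)),
    batch_id = vapply(sim$cohort, function(cs) cs$batch_id, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth(sim$truth, file.path(dir, "truth.tsv"))
  utils::write.table(sim$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Loads every `*.callstats.tsv` in a directory and, when a `samples.tsv`
#' manifest is present, restores each sample's patient and batch
#' assignment.
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled in
#'   the same layout).
#' @return List of `lbseq_calls` objects.
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "callstats\\.tsv$", full.names = TRUE)
  cohort <- lapply(files, read_callstats)
  manifest_path <- file.path(dir, "samples.tsv")
  if (file.exists(manifest_path)) {
    manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
    idx <- match(vapply(cohort, function(cs) cs$sample_id, character(1)),
                 manifest$sample_id)
    for (i in seq_along(cohort)) {
      if (!is.na(idx[i])) {
        cohort[[i]]$patient_id <- manifest$patient_id[idx[i]]
        cohort[[i]]$batch_id <- manifest$batch_id[idx[i]]
      }
    }
  }
  cohort
}
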