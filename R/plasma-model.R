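#' Binomial cfDNA sampling model and library-complexity arithmetic
#'
#' An aliquot of cfDNA of mass `m` nanograms contains
#' `n = floor(1000 m / haploid_mass_pg)` haploid genome equivalents
#' (molecules are discrete, so the count is floored). If tumour-derived
#' fragments make up a fraction `f` of circulating DNA, the number of
#' tumour fragments at any given locus in the aliquot is
#' `Binomial(n, f)`, and the probability that the aliquot captures at
#' least `k_min` tumour fragments is `1 - pbinom(k_min - 1, n, f)`. The
#' inverse problem — the smallest input mass achieving a target capture
#' probability — determines how much plasma DNA an assay must consume to
#' avoid allele dropout at low tumour fractions.
#'
#' The library-complexity chain follows the input molecules through
#' library construction: of the fragments entering preparation, a
#' retention fraction survives adapter ligation, amplification and
#' clean-up; a target of `target_bp` bases out of `genome_bp` captures the
#' proportional share of those molecules; and the unique-fragment coverage
#' ceiling is the on-target molecule count scaled by
#' `frag_len_bp / target_bp`.
#'
#' @name plasma_model
#' @keywords internal
NULL

#' Plasma sampling / complexity model configuration
#'
#' @param haploid_mass_pg Mass of one haploid genome, picograms
#'   (default 3.5).
#' @param tumour_fraction Fraction of circulating fragments that are
#'   tumour-derived (default 0.0005, i.e. 0.05%).
#' @param k_min Number of tumour fragments that must be captured
#'   (default 1).
#' @param retention_fraction Fraction of input fragments retained through
#'   library construction (default 0.43).
#' @param target_bp Captured target footprint in bases (default 17,500).
#' @param genome_bp Effective genome size in bases (default 2.86e9).
#' @param frag_len_bp Typical cfDNA fragment length (default 170).
#' @return A list of class `lbseq_plasma_config`.
#' @export
plasma_config <- function(haploid_mass_pg = 3.5, tumour_fraction = 5e-4,
                          k_min = 1L, retention_fraction = 0.43,
                          target_bp = 17500L, genome_bp = 2.86e9,
                          frag_len_bp = 170L) {
  stopifnot(haploid_mass_pg > 0, tumour_fraction > 0, tumour_fraction < 1,
            k_min >= 1, retention_fraction >= 0, retention_fraction <= 1,
            target_bp > 0, genome_bp > 0, frag_len_bp > 0)
  structure(list(haploid_mass_pg = haploid_mass_pg,
                 tumour_fraction = tumour_fraction,
                 k_min = as.integer(k_min),
                 retention_fraction = retention_fraction,
                 target_bp = target_bp, genome_bp = genome_bp,
                 frag_len_bp = frag_len_bp),
            class = "lbseq_plasma_config")
}

#' Haploid genome equivalents in a cfDNA mass
#'
#' @param mass_ng cfDNA mass in nanograms (>= 0).
#' @param cfg A [plasma_config()].
#' @return Integer count, `floor(mass_ng * 1000 / haploid_mass_pg)`.
#' @examples
#' genome_equivalents(83)  # 23714 genome equivalents at 3.5 pg each
#' @export
genome_equivalents <- function(mass_ng, cfg = plasma_config()) {
  stopifnot(all(mass_ng >= 0))
  # tolerance guards against masses that are an exact multiple of the
  # genome mass landing a float ulp below the integer
  floor(mass_ng * 1000 / cfg$haploid_mass_pg + 1e-9)
}

#' Probability of capturing tumour fragments in a cfDNA aliquot
#'
#' `P(X >= k_min)` for `X ~ Binomial(n, tumour_fraction)` with `n` the
#' genome equivalents in the aliquot. Monotone non-decreasing in mass and
#' tumour fraction, non-increasing in `k_min`.
#'
#' @inheritParams genome_equivalents
#' @return Probability in `[0, 1]`.
#' @examples
#' capture_probability(83, plasma_config(tumour_fraction = 5e-4))
#' @export
capture_probability <- function(mass_ng, cfg = plasma_config()) {
  n <- genome_equivalents(mass_ng, cfg)
  1 - stats::pbinom(cfg$k_min - 1L, n, cfg$tumour_fraction)
}

#' Smallest cfDNA input mass achieving a target capture probability
#'
#' For `k_min = 1` the closed form
#' `ceiling(log(1 - p) / log(1 - f))` genome equivalents applies; for
#' larger `k_min` the monotone binomial CDF is inverted by bisection on
#' the genome-equivalent count.
#'
#' @param p_target Target capture probability in (0, 1).
#' @param cfg A [plasma_config()].
#' @return Mass in nanograms (an integer number of genome equivalents).
#' @export
required_mass <- function(p_target, cfg = plasma_config()) {
  if (p_target >= 1 || p_target <= 0) {
    stop("'p_target' must lie strictly between 0 and 1", call. = FALSE)
  }
  f <- cfg$tumour_fraction
  if (cfg$k_min == 1L) {
    n <- ceiling(log(1 - p_target) / log(1 - f))
  } else {
    p_at <- function(n) 1 - stats::pbinom(cfg$k_min - 1L, n, f)
    hi <- max(cfg$k_min, ceiling(log(1 - p_target) / log(1 - f)))
    while (p_at(hi) < p_target) hi <- hi * 2L
    lo <- 0
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (p_at(mid) >= p_target) hi <- mid else lo <- mid
    }
    n <- hi
  }
  n * cfg$haploid_mass_pg / 1000
}

#' Library-complexity chain
#'
#' Follows input molecules through library construction: fragments
#' entering preparation (genome equivalents times fragments per genome),
#' fragments retained, unique on-target fragments, and the
#' unique-fragment coverage ceiling. `retained_fragments` may be supplied
#' directly (e.g. from a measured retention), bypassing the input-mass
#' arithmetic.
#'
#' @param input_ng cfDNA input mass in nanograms (ignored when
#'   `retained_fragments` is given).
#' @param cfg A [plasma_config()].
#' @param retained_fragments Optional directly specified count of
#'   fragments retained after library construction.
#' @return List with `total_fragments`, `retained_fragments`,
#'   `on_target_unique`, `unique_cov_ceiling`.
#' @examples
#' # 1.8e11 retained fragments over a 17.5 kb target in a 2.86 Gb genome
#' library_complexity(retained_fragments = 1.8e11)
#' @export
library_complexity <- function(input_ng = NULL, cfg = plasma_config(),
                               retained_fragments = NULL) {
  if (is.null(retained_fragments)) {
    if (is.null(input_ng) || input_ng <= 0) {
      stop("provide a positive 'input_ng' or 'retained_fragments'",
           call. = FALSE)
    }
    total <- genome_equivalents(input_ng, cfg) * cfg$genome_bp /
      cfg$frag_len_bp
    retained_fragments <- total * cfg$retention_fraction
  } else {
    total <- NA_real_
  }
  on_target <- retained_fragments * cfg$target_bp / cfg$genome_bp
  ceiling_x <- on_target * cfg$frag_len_bp / cfg$target_bp
  list(total_fragments = total, retained_fragments = retained_fragments,
       on_target_unique = on_target, unique_cov_ceiling = ceiling_x)
}

#' Unique-read percentage at a given raw coverage
#'
#' The fraction of reads at a locus that can be unique molecules, capped
#' at 100%, given the unique-fragment coverage ceiling.
#'
#' @param cov_ceiling Unique-fragment coverage ceiling (x).
#' @param depth Raw coverage (x), > 0.
#' @return Percent in `[0, 100]`.
#' @examples
#' unique_fraction(11000, 20000)   # ~55%
#' unique_fraction(11000, 100000)  # ~11%
#' @export
unique_fraction <- function(cov_ceiling, depth) {
  if (any(depth <= 0)) stop("'depth' must be > 0", call. = FALSE)
  pmin(100, 100 * cov_ceiling / depth)
}

#' Capture-panel footprint
#'
#' Footprint in bases of a probe panel: probes times probe length divided
#' by tiling density.
#'
#' @param n_probes Number of capture probes.
#' @param probe_len_nt Probe length in nucleotides.
#' @param tiling Tiling density (1 = non-overlapping end-to-end design).
#' @return Footprint in bases.
#' @examples
#' panel_footprint(146, 120)  # a ~17.5 kb five-gene exon panel
#' @export
panel_footprint <- function(n_probes, probe_len_nt = 120, tiling = 1) {
  stopifnot(n_probes > 0, probe_len_nt > 0, tiling > 0)
  n_probes * probe_len_nt / tiling
}
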