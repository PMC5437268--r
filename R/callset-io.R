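#' Candidate-variant call sets and their tab-separated interchange format
#'
#' A *call set* holds all candidate substitution calls for one plasma sample,
#' together with sample metadata. Calls live in a data frame with one row per
#' candidate and columns:
#'
#' * `contig`, `position` — chromosome name and 1-based coordinate
#'   (VCF/call-stats convention),
#' * `ref_allele`, `alt_allele` — uppercase single bases, unequal,
#' * `t_ref_count`, `t_alt_count` — reference/alternate read counts,
#' * `tumour_f` — allele fraction in `[0, 1]`,
#' * `t_lod` — tumour LOD score (log10 units),
#' * `judgement` — `"KEEP"` or `"REJECT"` (the upstream caller's verdict),
#' * `pop_af` — optional maximum population allele frequency across
#'   annotation databases (`NA` when unannotated),
#' * `gene`, `protein_change` — optional annotations,
#' * `flagged` — `TRUE` for rows excluded from analysis (non-single-base
#'   alleles, or count/fraction inconsistency beyond 0.5 reads).
#'
#' The on-disk dialect is a tab-separated table with header
#' `sample_id, contig, position, ref_allele, alt_allele, t_ref_count,
#' t_alt_count, tumour_f, t_lod_fstar, judgement, pop_af, gene,
#' protein_change`; lines starting with `#` are comments. Missing optional
#' fields serialize as empty strings.
#'
#' @name callset_io
#' @keywords internal
NULL

.CALL_COLUMNS <- c("contig", "position", "ref_allele", "alt_allele",
                   "t_ref_count", "t_alt_count", "tumour_f", "t_lod",
                   "judgement", "pop_af", "gene", "protein_change", "flagged")

.empty_calls <- function() {
  data.frame(contig = character(), position = integer(),
             ref_allele = character(), alt_allele = character(),
             t_ref_count = integer(), t_alt_count = integer(),
             tumour_f = numeric(), t_lod = numeric(),
             judgement = character(), pop_af = numeric(),
             gene = character(), protein_change = character(),
             flagged = logical(), stringsAsFactors = FALSE)
}

.normalize_calls <- function(calls) {
  n <- nrow(calls)
  if (is.null(calls$pop_af)) calls$pop_af <- rep(NA_real_, n)
  for (col in c("gene", "protein_change")) {
    if (is.null(calls[[col]])) calls[[col]] <- rep(NA_character_, n)
  }
  if (is.null(calls$flagged)) calls$flagged <- rep(FALSE, n)
  missing_cols <- setdiff(.CALL_COLUMNS, names(calls))
  if (length(missing_cols)) {
    stop("call table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  calls <- calls[.CALL_COLUMNS]
  calls$position <- as.integer(calls$position)
  calls$t_ref_count <- as.integer(calls$t_ref_count)
  calls$t_alt_count <- as.integer(calls$t_alt_count)
  rownames(calls) <- NULL
  calls
}

.flag_invalid_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  bad_allele <- !grepl("^[ACGT]$", calls$ref_allele) |
    !grepl("^[ACGT]$", calls$alt_allele) |
    calls$ref_allele == calls$alt_allele
  depth <- calls$t_alt_count + calls$t_ref_count
  inconsistent <- abs(calls$tumour_f * depth - calls$t_alt_count) > 0.5
  calls$flagged <- calls$flagged | bad_allele | inconsistent
  calls
}

#' Construct a sample call set
#'
#' @param sample_id Non-empty sample identifier.
#' @param calls Data frame of candidate calls (see [callset_io]); may have
#'   zero rows. Optional columns `pop_af`, `gene`, `protein_change`,
#'   `flagged` are filled with `NA`/`FALSE` when absent.
#' @param patient_id Patient identifier (defaults to `sample_id`).
#' @param batch_id Sequencing/capture batch label.
#' @param input_mass_ng Optional cfDNA input mass in nanograms.
#' @return An object of class `lbseq_calls`.
#' @examples
#' calls <- data.frame(contig = "chr1", position = 100L,
#'                     ref_allele = "A", alt_allele = "T",
#'                     t_ref_count = 95L, t_alt_count = 5L,
#'                     tumour_f = 0.05, t_lod = 12, judgement = "KEEP")
#' sample_callset("S01", calls)
#' @export
sample_callset <- function(sample_id, calls = .empty_calls(),
                           patient_id = sample_id, batch_id = NA_character_,
                           input_mass_ng = NA_real_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            nzchar(sample_id), is.data.frame(calls))
  if (!is.na(input_mass_ng) && input_mass_ng < 0) {
    stop("'input_mass_ng' must be >= 0", call. = FALSE)
  }
  calls <- .normalize_calls(calls)
  bad_judgement <- !(calls$judgement %in% c("KEEP", "REJECT"))
  if (any(bad_judgement)) {
    warning(sum(bad_judgement), " call(s) with judgement outside ",
            "{KEEP, REJECT} mapped to REJECT", call. = FALSE)
    calls$judgement[bad_judgement] <- "REJECT"
  }
  calls <- .flag_invalid_calls(calls)
  if (any(calls$position < 1, na.rm = TRUE)) {
    stop("'position' must be >= 1", call. = FALSE)
  }
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 batch_id = batch_id, input_mass_ng = input_mass_ng,
                 calls = calls),
            class = "lbseq_calls")
}

#' @export
print.lbseq_calls <- function(x, ...) {
  cat("LB-Seq call set:", x$sample_id,
      sprintf("(patient %s, batch %s)\n", x$patient_id, x$batch_id))
  cat("  candidate calls:", nrow(x$calls),
      sprintf("(%d KEEP, %d flagged)\n",
              sum(x$calls$judgement == "KEEP"), sum(x$calls$flagged)))
  if (!is.na(x$input_mass_ng)) {
    cat("  cfDNA input mass:", x$input_mass_ng, "ng\n")
  }
  invisible(x)
}

#' Locus keys for call/truth tables
#'
#' Collapses `contig:position:ref>alt` into a single string key used for
#' exact-locus matching between call sets and truth sets.
#'
#' @param x Data frame with columns `contig`, `position`, `ref_allele`,
#'   `alt_allele`.
#' @return Character vector of keys.
#' @export
locus_key <- function(x) {
  paste0(x$contig, ":", x$position, ":", x$ref_allele, ">", x$alt_allele)
}

#' Read a call-stats table
#'
#' Parses the tab-separated call-stats dialect described in [callset_io].
#' Rows whose counts or positions fail to parse as numbers are dropped from
#' the call table but recorded, with their file line numbers, in the
#' `parse_errors` attribute of the returned object's `calls` element, so
#' `rows in = calls + parse errors` always holds. Rows with non-substitution
#' alleles or inconsistent count/fraction fields are loaded but `flagged`.
#'
#' @param path Path to a call-stats TSV.
#' @return An `lbseq_calls` object.
#' @seealso [write_callstats()]
#' @export
read_callstats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  file_line <- which(is_data)
  if (!length(file_line)) stop("no header row in ", path, call. = FALSE)
  raw <- utils::read.delim(text = lines[is_data], colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  required <- c("sample_id", "contig", "position", "ref_allele", "alt_allele",
                "t_ref_count", "t_alt_count", "tumour_f", "t_lod_fstar",
                "judgement")
  for (col in required) {
    if (!col %in% names(raw)) {
      stop("missing required column '", col, "' in ", path, call. = FALSE)
    }
  }
  data_lines <- file_line[-1L]  # file line number of each data row

  num <- function(x) suppressWarnings(as.numeric(x))
  position <- num(raw$position)
  t_ref <- num(raw$t_ref_count)
  t_alt <- num(raw$t_alt_count)
  tumour_f <- num(raw$tumour_f)
  t_lod <- num(raw$t_lod_fstar)
  bad <- is.na(position) | is.na(t_ref) | is.na(t_alt) | is.na(tumour_f) |
    is.na(t_lod)
  parse_errors <- data.frame(line = data_lines[bad],
                             reason = rep("non-numeric required field",
                                          sum(bad)),
                             stringsAsFactors = FALSE)

  keep <- !bad
  opt_num <- function(col) {
    if (is.null(raw[[col]])) return(rep(NA_real_, sum(keep)))
    v <- raw[[col]][keep]
    out <- num(v)
    out[!nzchar(v)] <- NA_real_
    out
  }
  opt_chr <- function(col) {
    if (is.null(raw[[col]])) return(rep(NA_character_, sum(keep)))
    v <- raw[[col]][keep]
    v[!nzchar(v)] <- NA_character_
    v
  }
  calls <- data.frame(contig = raw$contig[keep],
                      position = as.integer(position[keep]),
                      ref_allele = raw$ref_allele[keep],
                      alt_allele = raw$alt_allele[keep],
                      t_ref_count = as.integer(t_ref[keep]),
                      t_alt_count = as.integer(t_alt[keep]),
                      tumour_f = tumour_f[keep],
                      t_lod = t_lod[keep],
                      judgement = raw$judgement[keep],
                      pop_af = opt_num("pop_af"),
                      gene = opt_chr("gene"),
                      protein_change = opt_chr("protein_change"),
                      stringsAsFactors = FALSE)
  sample_ids <- unique(raw$sample_id[keep])
  if (length(sample_ids) > 1L) {
    stop("call-stats file contains more than one sample_id: ",
         paste(sample_ids, collapse = ", "), call. = FALSE)
  }
  if (!length(sample_ids)) sample_ids <- sub("\\.[^.]*$", "", basename(path))
  out <- sample_callset(sample_ids, calls)
  attr(out$calls, "parse_errors") <- parse_errors
  out
}

#' Write a call-stats table
#'
#' Serializes an `lbseq_calls` object in the dialect read by
#' [read_callstats()], with a stable column order. Numeric fields are written
#' with 17 significant digits so that a read/write round trip reproduces the
#' stored doubles exactly; missing optional fields become empty strings.
#'
#' @param callset An `lbseq_calls` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_callstats <- function(callset, path) {
  stopifnot(inherits(callset, "lbseq_calls"))
  calls <- callset$calls
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  fmt_int <- function(x) ifelse(is.na(x), "", sprintf("%d", x))
  fmt_chr <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(sample_id = rep(callset$sample_id, nrow(calls)),
                    contig = calls$contig,
                    position = fmt_int(calls$position),
                    ref_allele = calls$ref_allele,
                    alt_allele = calls$alt_allele,
                    t_ref_count = fmt_int(calls$t_ref_count),
                    t_alt_count = fmt_int(calls$t_alt_count),
                    tumour_f = fmt_num(calls$tumour_f),
                    t_lod_fstar = fmt_num(calls$t_lod),
                    judgement = calls$judgement,
                    pop_af = fmt_num(calls$pop_af),
                    gene = fmt_chr(calls$gene),
                    protein_change = fmt_chr(calls$protein_change),
                    stringsAsFactors = FALSE)
  if (!nrow(calls)) {
    out <- out[0L, , drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bone-marrow truth set
#'
#' The truth set lists, per patient, the somatic mutations established from
#' bone-marrow tumour DNA together with their bone-marrow allele fractions.
#' Expected columns: `patient_id, contig, position, ref_allele, alt_allele,
#' bm_af, source`; `#` comment lines allowed. Duplicate `(patient, locus)`
#' rows and allele fractions outside `[0, 1]` are rejected.
#'
#' @param path Path to a truth TSV.
#' @return A data frame of class `lbseq_truth`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  truth <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  required <- c("patient_id", "contig", "position", "ref_allele",
                "alt_allele", "bm_af")
  for (col in required) {
    if (!col %in% names(truth)) {
      stop("missing required column '", col, "' in ", path, call. = FALSE)
    }
  }
  if (is.null(truth$source)) truth$source <- NA_character_
  as_truth(truth)
}

#' Validate and class a truth-set data frame
#'
#' @param truth Data frame with columns `patient_id, contig, position,
#'   ref_allele, alt_allele, bm_af` (and optionally `source`).
#' @return The same data frame, validated, with class `lbseq_truth`.
#' @export
as_truth <- function(truth) {
  stopifnot(is.data.frame(truth))
  if (is.null(truth$source)) truth$source <- NA_character_
  key <- paste(truth$patient_id, locus_key(truth))
  if (anyDuplicated(key)) {
    stop("duplicate (patient, locus) truth record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (any(truth$bm_af < 0 | truth$bm_af > 1)) {
    stop("'bm_af' outside [0, 1]", call. = FALSE)
  }
  truth$position <- as.integer(truth$position)
  rownames(truth) <- NULL
  class(truth) <- c("lbseq_truth", "data.frame")
  truth
}

#' Write a truth set
#'
#' @param truth An `lbseq_truth` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "lbseq_truth"))
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
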