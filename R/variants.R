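#' Align two versions of a genome segment-by-segment
#'
#' Banded global alignment of each segment pair (consensus versus consensus,
#' e.g. the same virus recovered in two sampling years). Identical inputs
#' yield gap-free all-match alignments.
#'
#' The gap penalty is deliberately strong (default -8): two consensus
#' versions of the same segment differ by substitutions far more often than
#' by indels, and a weak gap penalty would occasionally re-align dense
#' substitution clusters as spurious gap columns.
#'
#' @param a,b `truth_genome` objects or named character vectors with the
#'   same segment roster.
#' @param band band half-width in nt; per-segment length difference must not
#'   exceed it.
#' @param gap gap score per nt for the banded global alignment.
#' @return named list (per segment) of alignment results from [nw_align()],
#'   each with the two input sequences attached as `seq_a`, `seq_b`.
#' @export
align_versions <- function(a, b, band = 50L, gap = -8) {
  seqs_a <- if (inherits(a, "truth_genome")) a$segments else as_seq_chr(a, "a")
  seqs_b <- if (inherits(b, "truth_genome")) b$segments else as_seq_chr(b, "b")
  if (!setequal(names(seqs_a), names(seqs_b)))
    stop("segment rosters differ between the two genome versions")
  out <- lapply(names(seqs_a), function(id) {
    if (abs(nchar(seqs_a[[id]]) - nchar(seqs_b[[id]])) > band)
      stop("length difference exceeds band for segment ", id)
    al <- nw_align(seqs_a[[id]], seqs_b[[id]], gap = gap, band = band)
    al$seq_a <- seqs_a[[id]]
    al$seq_b <- seqs_b[[id]]
    al
  })
  stats::setNames(out, names(seqs_a))
}

#' Call single-nucleotide variants from version alignments
#'
#' One record per mismatch column of the per-segment alignments; gap columns
#' are excluded (no indel calling). Positions are 0-based on the first
#' genome version.
#'
#' @param alignments output of [align_versions()].
#' @return data.frame with `segment_id`, `position`, `ref_base`, `alt_base`,
#'   `klass` (`transition` for A<->G / C<->T, else `transversion`).
#' @export
call_snvs <- function(alignments) {
  out <- lapply(names(alignments), function(id) {
    al <- alignments[[id]]
    ok <- !is.na(al$a_pos) & !is.na(al$b_pos)
    ap <- al$a_pos[ok]; bp <- al$b_pos[ok]
    ra <- substring(al$seq_a, ap, ap)
    rb <- substring(al$seq_b, bp, bp)
    mm <- ra != rb
    if (!any(mm)) return(NULL)
    data.frame(segment_id = id, position = ap[mm] - 1L,
               ref_base = ra[mm], alt_base = rb[mm],
               klass = ifelse(is_transition(ra[mm], rb[mm]),
                              "transition", "transversion"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(segment_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      klass = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion summary
#'
#' @param variants data.frame from [call_snvs()].
#' @return list with `n`, `ti`, `tv` and `ti_percent`
#'   (`ti / n * 100`; `NA` when `n = 0`).
#' @export
titv_summary <- function(variants) {
  n <- nrow(variants)
  ti <- sum(variants$klass == "transition")
  list(n = n, ti = ti, tv = n - ti,
       ti_percent = if (n > 0L) 100 * ti / n else NA_real_)
}

#' Write variants as minimal VCF
#'
#' Emits CHROM / POS (1-based) / REF / ALT records with the
#' transition/transversion class in INFO.
#'
#' @param variants data.frame from [call_snvs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=KLASS,Number=1,Type=String,Description=\"transition or transversion\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tKLASS=%s",
                       variants$segment_id, variants$position + 1L,
                       variants$ref_base, variants$alt_base,
                       variants$klass), con)
  }
  invisible(path)
}

#' Check a deposited genome roster
#'
#' Verifies that a genome FASTA (e.g. segments retrieved from a sequence
#' repository) has the expected segment count and summed length. Used to
#' confirm deposited multi-segment genomes against their published totals.
#'
#' @param fasta path to a FASTA of genome segments.
#' @param expected_segments expected number of segments (or `NULL` to skip).
#' @param expected_length expected summed length in nt (or `NULL` to skip).
#' @return list with `n_segments`, `total_length` and logical `ok`.
#' @export
check_genome_roster <- function(fasta, expected_segments = NULL,
                                expected_length = NULL) {
  seqs <- read_fasta(fasta)
  n <- length(seqs)
  tot <- sum(nchar(seqs))
  ok <- TRUE
  if (!is.null(expected_segments)) ok <- ok && n == expected_segments
  if (!is.null(expected_length)) ok <- ok && tot == expected_length
  list(n_segments = n, total_length = tot, ok = ok)
}
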