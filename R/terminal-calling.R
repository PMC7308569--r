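#' Pipeline configuration
#'
#' Houses every numeric rule of the analysis. Defaults follow the screening
#' and validation thresholds of the FLDS virome procedure: contigs are kept
#' at >= 500 bp and >= 3x mean coverage; a terminal end is called when more
#' than 10 reads (i.e. >= 11) define the same terminal position; RdRp OTUs
#' are clustered at 90% nucleotide identity with a > 1.5 kb length filter;
#' genome sets require within-group GC spread < 5 percentage points, no
#' cross-member ORF pair above 50% amino-acid identity, and coverage
#' dominance above 1,000x; hosts are assigned when a virus exceeds 0.1% of
#' non-rRNA reads in the ssRNA-seq library.
#'
#' @param min_contig_len minimum contig length in nt (kept if `>=`).
#' @param min_mean_cov minimum mean coverage in x (kept if `>=`).
#' @param terminal_min_reads reads required at a terminal position (called if
#'   `>=`; default 11 encodes the strict "> 10 reads" rule).
#' @param terminal_tol_w tolerance window W: reads within W positions of the
#'   contig end count toward the terminal pile-up (default 0 = exact end).
#' @param terminal_window nt window used for terminal-sequence comparison.
#' @param terminal_identity grouping threshold (fraction) that both terminal
#'   windows must reach for two segments to be linked.
#' @param otu_identity nucleotide identity (fraction) for OTU membership.
#' @param otu_min_len OTU length filter in nt (kept if strictly greater).
#' @param dominance_cov coverage dominance threshold in x (strict `>`).
#' @param gc_max_diff maximum within-set GC spread in percentage points
#'   (valid if strictly less).
#' @param orf_sim_max maximum cross-member ORF identity in percent (failure
#'   if strictly greater).
#' @param host_min_frac host-assignment threshold in percent of non-rRNA
#'   reads (assigned if strictly greater).
#' @param min_identity read-mapping identity threshold (fraction).
#' @param kmer_k k-mer length for mapping seeds and read classification.
#' @param kmer_containment k-mer containment threshold for read
#'   classification.
#' @param kmer_stride stride when sampling read k-mers during classification.
#' @param min_orf_aa minimum ORF length in amino acids.
#' @param evalue_max recorded similarity-search threshold (provenance only;
#'   no database search is performed by this package).
#' @return object of class `flds_config`.
#' @export
flds_config <- function(min_contig_len = 500L,
                        min_mean_cov = 3,
                        terminal_min_reads = 11L,
                        terminal_tol_w = 0L,
                        terminal_window = 20L,
                        terminal_identity = 0.80,
                        otu_identity = 0.90,
                        otu_min_len = 1500L,
                        dominance_cov = 1000,
                        gc_max_diff = 5,
                        orf_sim_max = 50,
                        host_min_frac = 0.1,
                        min_identity = 0.95,
                        kmer_k = 21L,
                        kmer_containment = 0.3,
                        kmer_stride = 5L,
                        min_orf_aa = 100L,
                        evalue_max = 1e-5) {
  cfg <- list(min_contig_len = as.integer(min_contig_len),
              min_mean_cov = min_mean_cov,
              terminal_min_reads = as.integer(terminal_min_reads),
              terminal_tol_w = as.integer(terminal_tol_w),
              terminal_window = as.integer(terminal_window),
              terminal_identity = terminal_identity,
              otu_identity = otu_identity,
              otu_min_len = as.integer(otu_min_len),
              dominance_cov = dominance_cov,
              gc_max_diff = gc_max_diff,
              orf_sim_max = orf_sim_max,
              host_min_frac = host_min_frac,
              min_identity = min_identity,
              kmer_k = as.integer(kmer_k),
              kmer_containment = kmer_containment,
              kmer_stride = as.integer(kmer_stride),
              min_orf_aa = as.integer(min_orf_aa),
              evalue_max = evalue_max)
  num <- unlist(cfg[c("min_contig_len", "min_mean_cov", "terminal_min_reads",
                      "terminal_window", "otu_min_len", "dominance_cov",
                      "gc_max_diff", "orf_sim_max", "host_min_frac",
                      "kmer_k", "min_orf_aa", "evalue_max")])
  if (any(num <= 0)) stop("all thresholds must be strictly positive")
  fr <- unlist(cfg[c("otu_identity", "min_identity", "kmer_containment")])
  if (any(fr <= 0 | fr > 1)) stop("identity fractions must lie in (0, 1]")
  if (cfg$terminal_tol_w < 0L) stop("terminal_tol_w must be >= 0")
  structure(cfg, class = "flds_config")
}

#' Call terminal ends from a coverage profile
#'
#' A 5' terminus is called when at least `terminal_min_reads` alignments
#' start at contig position 0 (within the optional tolerance window
#' `terminal_tol_w`), and a 3' terminus when at least that many alignments
#' end at the last base. The default threshold of 11 encodes the rule that
#' more than 10 reads must define the same terminal position.
#'
#' @param profile a `coverage_profile`.
#' @param config a [flds_config()].
#' @return named logical vector `c(terminus5, terminus3)`.
#' @export
call_termini <- function(profile, config = flds_config()) {
  stopifnot(inherits(profile, "coverage_profile"))
  w <- config$terminal_tol_w
  n <- profile$length
  i5 <- seq_len(min(w + 1L, n))
  i3 <- seq.int(max(1L, n - w), n)
  c(terminus5 = sum(profile$starts5[i5]) >= config$terminal_min_reads,
    terminus3 = sum(profile$ends3[i3]) >= config$terminal_min_reads)
}

#' Screen contigs and classify potential genome segments
#'
#' Applies the contig screen (length and mean coverage, both read as
#' "at least") and, for passing contigs, calls terminal ends from the
#' read-end pileups. Contigs failing the screen are `discarded`; contigs
#' with both termini called are `full_length` (potential genome segments);
#' the rest are `partial`.
#'
#' @param contigs named character vector (or `DNAStringSet`) of contigs.
#' @param profiles named list of `coverage_profile` objects (one per contig).
#' @param config a [flds_config()].
#' @return data.frame with one row per contig: `seq_id`, `length`,
#'   `mean_coverage`, `starts5_at_0`, `ends3_at_end`, `terminus5`,
#'   `terminus3`, `status`.
#' @export
screen_contigs <- function(contigs, profiles, config = flds_config()) {
  contigs <- as_seq_chr(contigs, "contigs")
  missing <- setdiff(names(contigs), names(profiles))
  if (length(missing))
    stop("missing coverage profile for contig(s): ",
         paste(missing, collapse = ", "))
  rows <- lapply(names(contigs), function(id) {
    pr <- profiles[[id]]
    stopifnot(inherits(pr, "coverage_profile"))
    len <- nchar(contigs[[id]])
    if (pr$length != len)
      stop("profile length does not match contig length for ", id)
    keep <- len >= config$min_contig_len && pr$mean_coverage >= config$min_mean_cov
    if (!keep) {
      t5 <- NA; t3 <- NA; status <- "discarded"
    } else {
      tt <- call_termini(pr, config)
      t5 <- tt[["terminus5"]]; t3 <- tt[["terminus3"]]
      status <- if (t5 && t3) "full_length" else "partial"
    }
    data.frame(seq_id = id, length = len, mean_coverage = pr$mean_coverage,
               starts5_at_0 = pr$starts5[1], ends3_at_end = pr$ends3[len],
               terminus5 = t5, terminus3 = t3, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize segment classification
#'
#' @param records data.frame from [screen_contigs()].
#' @return named integer vector with counts `full_length`, `partial`,
#'   `discarded` (summing to `nrow(records)`).
#' @export
summarize_segments <- function(records) {
  stopifnot(nrow(records) > 0L)
  out <- c(full_length = 0L, partial = 0L, discarded = 0L)
  tab <- table(records$status)
  out[names(tab)] <- as.integer(tab)
  out
}
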