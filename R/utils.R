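#' @useDynLib fldsvirome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Coerce DNAStringSet / character to a named character vector of sequences.
as_seq_chr <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop(what, " must be a character vector or XStringSet")
  x
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of DNA sequences (ACGTN alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC content of nucleotide sequences
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC percentages in `[0, 100]`.
#' @export
gc_percent <- function(x) {
  ss <- Biostrings::DNAStringSet(x)
  f <- Biostrings::alphabetFrequency(ss, baseOnly = TRUE)
  tot <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  100 * (f[, "G"] + f[, "C"]) / pmax(tot, 1L)
}

# All k-mers of each sequence as a data.table(seq (index), pos (0-based), kmer).
kmer_table <- function(seqs, k, stride = 1L) {
  stopifnot(k >= 1L)
  idx <- seq_along(seqs)
  lens <- nchar(seqs)
  keep <- lens >= k
  out <- vector("list", sum(keep))
  ii <- 0L
  for (i in idx[keep]) {
    starts <- seq.int(1L, lens[i] - k + 1L, by = stride)
    ii <- ii + 1L
    out[[ii]] <- data.table::data.table(
      seq = i, pos = starts - 1L,
      kmer = substring(seqs[i], starts, starts + k - 1L))
  }
  if (ii == 0L)
    return(data.table::data.table(seq = integer(), pos = integer(),
                                  kmer = character()))
  data.table::rbindlist(out)
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with linear gap penalty, used for
#' terminal-window comparison, protein identity, OTU nucleotide identity and
#' genome-version comparison. Ties in the traceback are resolved
#' deterministically (diagonal, then gap-in-second, then gap-in-first).
#'
#' @param a,b sequences (single strings; nucleotide or protein).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @param band optional band half-width in residues; `0` disables banding.
#' @return list with `score`, `matches`, `columns`, `gaps`,
#'   `identity` (= matches / columns * 100) and the aligned 1-based position
#'   vectors `a_pos`, `b_pos` (`NA` marks a gap).
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2, band = 0) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  res <- .nw_align_cpp(as.character(a), as.character(b),
                       match = match, mismatch = mismatch, gap = gap,
                       band = as.integer(band), traceback = TRUE)
  res$identity <- if (res$columns > 0) 100 * res$matches / res$columns else NA_real_
  res
}

# Percent identity of a global alignment of two sequences.
nw_identity <- function(a, b, ...) nw_align(a, b, ...)$identity

#' Write sequences to FASTA / FASTQ
#'
#' Thin wrappers around [Biostrings::writeXStringSet()]; FASTQ records get a
#' constant high quality string (the simulator does not model base quality).
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(as_seq_chr(seqs))
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  seqs <- as_seq_chr(seqs)
  ss <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fasta"))
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
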