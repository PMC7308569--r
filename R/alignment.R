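#' Map reads to reference sequences
#'
#' Lightweight substitution-only mapper for synthetic FLDS data: exact 21-mer
#' seeding followed by ungapped full-length placement with mismatch counting,
#' on both strands. Each read is reported at most once (best hit = fewest
#' mismatches; ties broken by lexicographically smallest reference id, then
#' smallest start, then "+" strand). A read is mapped only if it fits
#' entirely inside the reference and its identity
#' `1 - mismatches / read length` reaches `min_identity`. Real-data users
#' should import external alignments with [read_sam()] instead.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param refs named character vector (or `DNAStringSet`) of references.
#' @param min_identity minimum identity fraction in `(0.5, 1]`.
#' @param k seed k-mer length (default 21).
#' @param n_seeds number of seed offsets tried per read and strand.
#' @return data.frame with columns `read_id`, `ref_id`, 0-based half-open
#'   `start`/`end`, `strand` and `n_mismatches`; unmapped reads are absent.
#' @export
map_reads <- function(reads, refs, min_identity = 0.95, k = 21L,
                      n_seeds = 5L) {
  refs <- as_seq_chr(refs, "refs")
  if (length(refs) == 0L) stop("refs must be nonempty")
  reads <- as_seq_chr(reads, "reads")
  empty <- data.frame(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  if (min_identity <= 0.5 || min_identity > 1)
    stop("min_identity must lie in (0.5, 1]")
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))

  index <- kmer_table(refs, k)            # seq (ref index), pos, kmer
  data.table::setkey(index, kmer)

  lens <- nchar(reads)
  cand_all <- vector("list", 2L)
  for (o in 1:2) {
    oriented <- if (o == 1L) reads else revcomp(reads)
    # evenly spaced seed offsets per read (1-based)
    offs <- lapply(lens, function(L) {
      if (L < k) return(integer(0))
      unique(as.integer(round(seq(1L, L - k + 1L, length.out = n_seeds))))
    })
    nof <- lengths(offs)
    if (sum(nof) == 0L) next
    dt <- data.table::data.table(
      read = rep(seq_along(reads), nof),
      off = unlist(offs))
    dt[, kmer := substring(oriented[read], off, off + k - 1L)]
    hits <- index[dt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(hits) == 0L) next
    hits[, start := pos - (off - 1L)]
    hits <- unique(hits[, .(read, ref = seq, start)])
    hits[, strand := if (o == 1L) "+" else "-"]
    hits[, oriented_seq := oriented[read]]
    cand_all[[o]] <- hits
  }
  cand <- data.table::rbindlist(cand_all)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[start >= 0L & start + lens[read] <= nchar(refs)[ref]]
  if (nrow(cand) == 0L) return(empty)
  cand[, mm := .hamming_at_cpp(refs, ref, start, oriented_seq)]
  cand <- cand[!is.na(mm) & (1 - mm / lens[read]) >= min_identity]
  if (nrow(cand) == 0L) return(empty)
  cand[, ref_id := names(refs)[ref]]
  data.table::setorder(cand, read, mm, ref_id, start, strand)
  best <- cand[, .SD[1L], by = read]
  out <- data.frame(read_id = names(reads)[best$read],
                    ref_id = best$ref_id,
                    start = best$start,
                    end = best$start + lens[best$read],
                    strand = best$strand,
                    n_mismatches = best$mm,
                    stringsAsFactors = FALSE)
  out[order(match(out$read_id, names(reads))), , drop = FALSE]
}

#' Read and write minimal SAM
#'
#' Supports the minimal SAM dialect used by this package: `@SQ` header lines
#' and records with FLAG (0/4/16), 1-based POS and CIGAR restricted to
#' M/=/X/S operations. Soft clips are recorded in CIGAR but do not move the
#' alignment's terminal positions. Coordinates are converted between SAM
#' (1-based, closed) and the internal 0-based half-open convention at this
#' boundary only. Mismatch counts travel in the `NM:i:` tag.
#'
#' @param path SAM file path.
#' @param alignments data.frame as returned by [map_reads()].
#' @param refs named character vector of references (for `@SQ` lengths).
#' @return `read_sam()`: an alignments data.frame; `write_sam()`: `path`,
#'   invisibly.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "@"))
    stop("not a SAM file (missing header): ", path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_len <- integer(0)
  for (h in sq) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
    ref_len[sn] <- ln
  }
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next       # unmapped
    rname <- f[3]
    if (!rname %in% names(ref_len))
      stop("alignment to unknown reference: ", rname)
    pos <- as.integer(f[4])
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    if (length(ops) == 0L) stop("unparseable CIGAR: ", cig)
    opc <- substr(ops, nchar(ops), nchar(ops))
    opl <- as.integer(substr(ops, 1L, nchar(ops) - 1L))
    if (any(!opc %in% c("M", "=", "X", "S")))
      stop("unsupported CIGAR operation in: ", cig)
    ref_span <- sum(opl[opc %in% c("M", "=", "X")])
    nm <- 0L
    tags <- f[-(1:11)]
    nmtag <- tags[startsWith(tags, "NM:i:")]
    if (length(nmtag)) nm <- as.integer(sub("^NM:i:", "", nmtag[1]))
    out[[length(out) + 1L]] <- data.frame(
      read_id = f[1], ref_id = rname,
      start = pos - 1L, end = pos - 1L + ref_span,
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      n_mismatches = nm, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  bad <- res$end > ref_len[res$ref_id]
  if (any(bad)) stop("alignment interval exceeds reference length for ",
                     res$read_id[which(bad)[1]])
  res
}

#' @rdname read_sam
#' @export
write_sam <- function(alignments, refs, path) {
  refs <- as_seq_chr(refs, "refs")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  if (nrow(alignments)) {
    if (!all(alignments$ref_id %in% names(refs)))
      stop("alignment to unknown reference")
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       alignments$read_id,
                       ifelse(alignments$strand == "-", 16L, 0L),
                       alignments$ref_id,
                       alignments$start + 1L,
                       alignments$end - alignments$start,
                       alignments$n_mismatches), con)
  }
  invisible(path)
}

#' Per-base coverage with read start/end pileups
#'
#' Computes, for one reference, the per-position depth together with the
#' per-position counts of alignment 5'-most (`starts5`) and 3'-most (`ends3`)
#' reference positions. These end-position pileups are the signal the
#' terminal caller consumes. `mean_coverage` is the mean per-base depth over
#' the full reference length.
#'
#' @param alignments alignments data.frame; all rows must be on `ref_id`.
#' @param ref_len reference length in nt.
#' @param ref_id reference id.
#' @return object of class `coverage_profile`: list with `ref_id`, `length`,
#'   integer vectors `depth`, `starts5`, `ends3` (length `ref_len`) and
#'   `mean_coverage`.
#' @export
pileup <- function(alignments, ref_len, ref_id) {
  ref_len <- as.integer(ref_len)
  a <- alignments
  if (nrow(a) && !all(a$ref_id == ref_id))
    stop("alignments on other references passed to pileup for ", ref_id)
  if (nrow(a) && (any(a$start < 0L) || any(a$end > ref_len) ||
                  any(a$start >= a$end)))
    stop("alignment interval outside [0, ", ref_len, ") for ", ref_id)
  delta <- integer(ref_len + 1L)
  starts5 <- integer(ref_len)
  ends3 <- integer(ref_len)
  if (nrow(a)) {
    ts <- tabulate(a$start + 1L, nbins = ref_len + 1L)
    te <- tabulate(a$end + 1L, nbins = ref_len + 1L)
    delta <- ts - te
    starts5 <- tabulate(a$start + 1L, nbins = ref_len)
    ends3 <- tabulate(a$end, nbins = ref_len)
  }
  depth <- cumsum(delta[seq_len(ref_len)])
  structure(list(ref_id = ref_id, length = ref_len,
                 depth = as.integer(depth),
                 starts5 = as.integer(starts5),
                 ends3 = as.integer(ends3),
                 mean_coverage = sum(as.numeric(depth)) / ref_len),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s: %d nt, mean %.1fx, starts5[1]=%d, ends3[end]=%d\n",
              x$ref_id, x$length, x$mean_coverage,
              x$starts5[1], x$ends3[x$length]))
  invisible(x)
}

#' Coverage profiles for a set of contigs
#'
#' Convenience wrapper running [pileup()] per contig over one alignment set.
#'
#' @param alignments alignments data.frame (multiple references).
#' @param refs named character vector of contig sequences.
#' @return named list of `coverage_profile` objects, one per contig.
#' @export
pileup_all <- function(alignments, refs) {
  refs <- as_seq_chr(refs, "refs")
  out <- lapply(names(refs), function(id)
    pileup(alignments[alignments$ref_id == id, , drop = FALSE],
           nchar(refs[[id]]), id))
  stats::setNames(out, names(refs))
}
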