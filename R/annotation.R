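STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs on one strand of an oriented sequence: per frame, regions between
# in-frame stops; each region's ORF runs from its first ATG to the closing
# stop (included in the interval) or to the last complete codon.
orfs_one_strand <- function(seq, min_aa) {
  L <- nchar(seq)
  gcode <- Biostrings::GENETIC_CODE
  out <- list()
  for (frame in 0:2) {
    if (L < frame + 3L) next
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    bounds <- c(0L, stop_idx, length(codons) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L
      hi <- bounds[b + 1L] - 1L         # last coding codon before stop/end
      if (hi < lo) next
      atg <- which(is_atg[lo:hi])
      if (length(atg) == 0L) next
      a0 <- lo + atg[1L] - 1L
      n_aa <- hi - a0 + 1L
      if (n_aa < min_aa) next
      terminated <- bounds[b + 1L] <= length(codons)
      cstart <- starts[a0]              # 1-based nt
      cend <- starts[hi] + 2L + (if (terminated) 3L else 0L)
      aa <- gcode[codons[a0:hi]]
      aa[is.na(aa)] <- "X"
      out[[length(out) + 1L]] <- data.frame(
        start = cstart - 1L, end = cend, strand = "+", frame = frame,
        protein = paste(aa, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find open reading frames
#'
#' Enumerates ORFs on both strands in all six frames under the standard
#' genetic code: an ORF starts at the first ATG following the previous
#' in-frame stop and runs to the next in-frame stop (included in the
#' interval) or to the sequence end. Coordinates are 0-based half-open on
#' the forward strand; `frame` is the 0/1/2 offset on the ORF's own strand.
#'
#' @param sequence nucleotide string (ACGTN alphabet).
#' @param min_aa minimum protein length in amino acids (default 100).
#' @return data.frame sorted by interval length descending: `start`, `end`,
#'   `strand`, `frame`, `protein` (stop codon not included in the protein).
#' @export
find_orfs <- function(sequence, min_aa = 100L) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains non-ACGTN characters")
  if (min_aa < 2L) stop("min_aa must be >= 2")
  L <- nchar(sequence)
  fwd <- orfs_one_strand(sequence, min_aa)
  rev <- orfs_one_strand(revcomp(sequence), min_aa)
  if (nrow(rev)) {
    new_start <- L - rev$end
    rev$end <- L - rev$start
    rev$start <- new_start
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  out[order(-(out$end - out$start), out$start, out$strand), , drop = FALSE]
}

#' @rdname find_orfs
#' @param sequences named character vector of sequences.
#' @return `find_orfs_all()`: the same table with a leading `parent_id`
#'   column.
#' @export
find_orfs_all <- function(sequences, min_aa = 100L) {
  sequences <- as_seq_chr(sequences)
  out <- lapply(names(sequences), function(id) {
    o <- find_orfs(sequences[[id]], min_aa)
    if (nrow(o)) cbind(parent_id = id, o, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(parent_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' RdRp motif grammar
#'
#' The scanner's configurable motif table: motif C is the canonical
#' `[GSA]DD` triplet at the catalytic core; motif A (`D-x(4,5)-D`) and motif
#' B (`G-x(2,3)-T`) are the corroborating upstream polymerase motifs. The
#' residue patterns approximate the published RdRp signature set; the
#' grammar is isolated here so it can be swapped without touching the
#' scanner.
#'
#' @param motif_c,motif_a,motif_b regular expressions over amino acids.
#' @param max_span maximum A-to-C separation in aa.
#' @return named list used by [scan_rdrp_motifs()].
#' @export
rdrp_motif_grammar <- function(motif_c = "[GSA]DD",
                               motif_a = "D.{4,5}D",
                               motif_b = "G.{2,3}T",
                               max_span = 150L) {
  list(motif_c = motif_c, motif_a = motif_a, motif_b = motif_b,
       max_span = as.integer(max_span))
}

#' Scan a protein for RdRp signature motifs
#'
#' Motif C is the first `[GSA]DD` occurrence; motifs A and B are searched in
#' the `max_span` residues upstream of C (B downstream of A when A is
#' found). A hit requires motif C plus at least one corroborating upstream
#' motif — an isolated GDD triplet is not reported.
#'
#' @param protein amino-acid string (>= 100 aa).
#' @param grammar a [rdrp_motif_grammar()].
#' @return `NULL` if no hit; otherwise a list with `motif_c_offset`
#'   (0-based aa position), `motif_c_seq`, `motif_a_found`, `motif_b_found`
#'   and `score` (number of motifs found).
#' @export
scan_rdrp_motifs <- function(protein, grammar = rdrp_motif_grammar()) {
  protein <- as.character(protein)
  if (nchar(protein) < 100L) return(NULL)
  cm <- regexpr(grammar$motif_c, protein)
  if (cm == -1L) return(NULL)
  c_off <- as.integer(cm)                 # 1-based
  win_lo <- max(1L, c_off - grammar$max_span)
  window <- substr(protein, win_lo, c_off - 1L)
  am <- regexpr(grammar$motif_a, window)
  a_found <- am != -1L
  b_region <- if (a_found) substr(window, as.integer(am) + 1L, nchar(window))
              else window
  b_found <- grepl(grammar$motif_b, b_region)
  if (!a_found && !b_found) return(NULL)
  list(motif_c_offset = c_off - 1L,
       motif_c_seq = substr(protein, c_off, c_off + 2L),
       motif_a_found = a_found,
       motif_b_found = b_found,
       score = 1L + a_found + b_found)
}

#' Pairwise protein identity
#'
#' Percent identity (matches / alignment columns x 100) from a global
#' alignment with match +1, mismatch -1, gap -2.
#'
#' @param a,b amino-acid strings (nonempty).
#' @return percent identity in `[0, 100]`.
#' @export
protein_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("proteins must be nonempty")
  nw_identity(a, b)
}

#' Greedy centroid OTU clustering of RdRp sequences
#'
#' Reproduces centroid clustering at the nucleotide level: records at or
#' below the length filter are dropped; the rest are processed by length
#' descending (ties by id ascending); each record joins the first existing
#' centroid whose global-alignment nucleotide identity reaches
#' `otu_identity`, otherwise it founds a new OTU. Centroids are therefore
#' pairwise below the identity threshold.
#'
#' @param records named character vector of RdRp-encoding nucleotide
#'   sequences.
#' @param config a [flds_config()].
#' @return list of `rdrp_otu` objects (`otu_id`, `centroid_id`,
#'   `member_ids`).
#' @export
cluster_rdrp_otus <- function(records, config = flds_config()) {
  records <- as_seq_chr(records, "records")
  keep <- nchar(records) > config$otu_min_len
  records <- records[keep]
  if (length(records) == 0L) return(list())
  ord <- order(-nchar(records), names(records))
  records <- records[ord]
  thr <- 100 * config$otu_identity
  centroids <- character(0)
  members <- list()
  for (id in names(records)) {
    joined <- FALSE
    for (ci in seq_along(centroids)) {
      if (nw_identity(records[[id]], records[[centroids[ci]]]) >= thr) {
        members[[ci]] <- c(members[[ci]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, id)
      members[[length(centroids)]] <- id
    }
  }
  lapply(seq_along(centroids), function(i)
    structure(list(otu_id = sprintf("otu%03d", i),
                   centroid_id = centroids[i],
                   member_ids = members[[i]]), class = "rdrp_otu"))
}

#' @export
print.rdrp_otu <- function(x, ...) {
  cat(sprintf("rdrp_otu %s: centroid %s, %d member(s)\n",
              x$otu_id, x$centroid_id, length(x$member_ids)))
  invisible(x)
}

#' OTU table
#'
#' @param otus list of `rdrp_otu` objects.
#' @return data.frame with `otu_id`, `centroid_id`, `member_ids`
#'   (comma-separated) and `member_count`.
#' @export
otu_table <- function(otus) {
  if (length(otus) == 0L)
    return(data.frame(otu_id = character(), centroid_id = character(),
                      member_ids = character(), member_count = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(otus, function(o)
    data.frame(otu_id = o$otu_id, centroid_id = o$centroid_id,
               member_ids = paste(o$member_ids, collapse = ","),
               member_count = length(o$member_ids),
               stringsAsFactors = FALSE)))
}

#' Write ORFs as GFF3
#'
#' Minimal GFF3 emitter for the ORF table (one CDS feature per ORF, 1-based
#' closed coordinates per the GFF3 convention).
#'
#' @param orfs table from [find_orfs_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    writeLines(sprintf(
      "%s\tfldsvirome\tCDS\t%d\t%d\t.\t%s\t0\tID=orf%04d;frame=%d",
      orfs$parent_id, orfs$start + 1L, orfs$end, orfs$strand,
      seq_len(nrow(orfs)), orfs$frame), con)
  }
  invisible(path)
}
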