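# Containment of each read's sampled k-mers in one or more reference k-mer
# sets. Returns a data.table(read, target, containment).
kmer_containment <- function(reads, ref_kmers_by_target, k, stride) {
  rt <- kmer_table(reads, k, stride = stride)
  if (nrow(rt) == 0L)
    return(data.table::data.table(read = integer(), target = character(),
                                  containment = numeric()))
  n_kmers <- rt[, .N, by = seq][, stats::setNames(N, seq)]
  out <- lapply(names(ref_kmers_by_target), function(tg) {
    hits <- rt[kmer %chin% ref_kmers_by_target[[tg]], .N, by = seq]
    if (nrow(hits) == 0L) return(NULL)
    data.table::data.table(read = hits$seq, target = tg,
                           containment = hits$N / n_kmers[as.character(hits$seq)])
  })
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table::data.table(read = integer(), target = character(),
                                  containment = numeric())
  res
}

#' Classify reads as rRNA, viral, or other
#'
#' Reference k-mer containment classification (the deterministic, desk-scale
#' stand-in for an rRNA read filter): a read is rRNA if the fraction of its
#' sampled k-mers present in the rRNA reference k-mer set reaches
#' `kmer_containment`; otherwise it is assigned to the viral target with the
#' highest containment reaching the threshold; otherwise it counts as
#' "other". Viral references can be pooled into per-virus targets (e.g. all
#' segments of one genome set) via `target_of`.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param rrna_refs named character vector of rRNA reference sequences.
#' @param viral_refs named character vector of viral reference sequences
#'   (may be empty).
#' @param target_of optional named character vector mapping viral reference
#'   id to a pooled target id (default: each reference is its own target).
#' @param config a [flds_config()] (uses `kmer_k`, `kmer_containment`,
#'   `kmer_stride`).
#' @return object of class `read_class_counts`: `total`, `rrna`,
#'   `viral_per_target` (named integer), `other`, and `per_read`
#'   (data.frame `read_id`, `class`, `target`).
#' @export
classify_reads <- function(reads, rrna_refs, viral_refs,
                           target_of = NULL, config = flds_config()) {
  reads <- as_seq_chr(reads, "reads")
  rrna_refs <- as_seq_chr(rrna_refs, "rrna_refs")
  viral_refs <- as_seq_chr(viral_refs, "viral_refs")
  if (length(rrna_refs) == 0L) stop("rrna_refs must be nonempty")
  if (length(intersect(names(rrna_refs), names(viral_refs))))
    stop("reference sets must be disjoint by id")
  k <- config$kmer_k
  if (length(reads) && k > min(nchar(reads)))
    stop("k-mer length exceeds read length")
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
  if (is.null(target_of))
    target_of <- stats::setNames(names(viral_refs), names(viral_refs))

  # reference k-mer sets on both strands (reads are unstranded)
  ref_set <- function(seqs) unique(c(kmer_table(seqs, k)$kmer,
                                     kmer_table(revcomp(seqs), k)$kmer))
  sets <- list(.rrna = ref_set(rrna_refs))
  for (tg in unique(target_of)) {
    sets[[tg]] <- ref_set(viral_refs[names(target_of)[target_of == tg]])
  }
  cont <- kmer_containment(reads, sets, k, config$kmer_stride)
  cls <- rep("other", length(reads))
  tgt <- rep(NA_character_, length(reads))
  if (nrow(cont)) {
    thr <- config$kmer_containment
    rr <- cont[target == ".rrna" & containment >= thr]
    cls[rr$read] <- "rrna"
    vv <- cont[target != ".rrna" & containment >= thr &
                 !(read %in% rr$read)]
    if (nrow(vv)) {
      data.table::setorder(vv, read, -containment, target)
      vv <- vv[, .SD[1L], by = read]
      cls[vv$read] <- "viral"
      tgt[vv$read] <- vv$target
    }
  }
  viral_per_target <- stats::setNames(integer(length(unique(target_of))),
                                      unique(target_of))
  tb <- table(tgt[cls == "viral"])
  viral_per_target[names(tb)] <- as.integer(tb)
  structure(list(total = length(reads),
                 rrna = sum(cls == "rrna"),
                 viral_per_target = viral_per_target,
                 other = sum(cls == "other"),
                 per_read = data.frame(read_id = names(reads), class = cls,
                                       target = tgt, stringsAsFactors = FALSE)),
            class = "read_class_counts")
}

#' @export
print.read_class_counts <- function(x, ...) {
  cat(sprintf("read_class_counts: %d total; %d rRNA (%.1f%%), %d viral (%.2f%%), %d other\n",
              x$total, x$rrna, 100 * x$rrna / x$total,
              sum(x$viral_per_target),
              100 * sum(x$viral_per_target) / x$total, x$other))
  invisible(x)
}

#' Host assignment from viral abundance in ssRNA-seq
#'
#' Applies the abundance rule for putative infection of the sampled
#' organism: a virus whose reads exceed `host_min_frac` percent (strictly)
#' of the non-rRNA reads in a conventional RNA-seq library is called as
#' infecting the sampled host. Fractions are reported to 4 decimal places
#' worth of precision (values like 0.0025% are meaningful).
#'
#' @param counts a `read_class_counts` from [classify_reads()].
#' @param config a [flds_config()].
#' @return data.frame with `target_id`, `reads`, `frac_nonrrna` (percent)
#'   and logical `assigned`.
#' @export
host_assignment <- function(counts, config = flds_config()) {
  stopifnot(inherits(counts, "read_class_counts"))
  nonrrna <- counts$total - counts$rrna
  if (nonrrna <= 0L)
    stop("no non-rRNA reads: host-assignment fraction undefined")
  frac <- 100 * counts$viral_per_target / nonrrna
  data.frame(target_id = names(counts$viral_per_target),
             reads = unname(counts$viral_per_target),
             frac_nonrrna = unname(frac),
             assigned = unname(frac > config$host_min_frac),
             stringsAsFactors = FALSE)
}

#' SSU rRNA composition from mapped read counts
#'
#' Assigns rRNA-classified reads to the SSU reference with the highest k-mer
#' containment and reports per-reference fractions of all SSU-classified
#' reads (summing to 1). This mirrors composition estimation from mapped
#' read numbers on reconstructed SSU sequences.
#'
#' @param reads named character vector of reads (typically the full ssRNA-seq
#'   library).
#' @param ssu_refs named character vector of SSU rRNA reference sequences.
#' @param config a [flds_config()].
#' @return data.frame with `ref_id`, `reads`, `fraction`; zero rows (with a
#'   warning) when no read classifies as SSU.
#' @export
ssu_composition <- function(reads, ssu_refs, config = flds_config()) {
  reads <- as_seq_chr(reads, "reads")
  ssu_refs <- as_seq_chr(ssu_refs, "ssu_refs")
  stopifnot(length(ssu_refs) > 0L)
  k <- config$kmer_k
  sets <- lapply(names(ssu_refs), function(id)
    unique(c(kmer_table(ssu_refs[id], k)$kmer,
             kmer_table(revcomp(ssu_refs[id]), k)$kmer)))
  names(sets) <- names(ssu_refs)
  cont <- kmer_containment(reads, sets, k, config$kmer_stride)
  cont <- cont[containment >= config$kmer_containment]
  if (nrow(cont) == 0L) {
    warning("no SSU-classified reads")
    return(data.frame(ref_id = character(), reads = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  data.table::setorder(cont, read, -containment, target)
  best <- cont[, .SD[1L], by = read]
  counts <- stats::setNames(integer(length(ssu_refs)), names(ssu_refs))
  tb <- table(best$target)
  counts[names(tb)] <- as.integer(tb)
  data.frame(ref_id = names(counts), reads = unname(counts),
             fraction = unname(counts) / sum(counts),
             stringsAsFactors = FALSE)
}
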