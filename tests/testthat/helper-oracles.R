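# Independent oracles used to cross-check the package implementations.
# These are deliberately naive re-implementations (textbook dynamic
# programming, brute-force counting loops) kept separate from the package
# code paths they verify.

# Textbook Needleman-Wunsch with linear gap penalty, full score matrix and
# the same deterministic tie preference (diagonal, then up, then left).
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(3L, n + 1, m + 1)
  S[1, ] <- gap * (0:m); S[, 1] <- gap * (0:n)
  if (m > 0) P[1, 2:(m + 1)] <- 2L
  if (n > 0) P[2:(n + 1), 1] <- 1L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d <- S[i, j] + (if (A[i] == B[j]) match else mismatch)
    u <- S[i, j + 1] + gap
    l <- S[i + 1, j] + gap
    best <- d; code <- 0L
    if (u > best) { best <- u; code <- 1L }
    if (l > best) { best <- l; code <- 2L }
    S[i + 1, j + 1] <- best; P[i + 1, j + 1] <- code
  }
  i <- n; j <- m; matches <- 0L; columns <- 0L; gaps <- 0L
  while (i > 0 || j > 0) {
    code <- P[i + 1, j + 1]
    if (i > 0 && j > 0 && code == 0L) {
      if (A[i] == B[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && (code == 1L || j == 0)) {
      gaps <- gaps + 1L; i <- i - 1
    } else {
      gaps <- gaps + 1L; j <- j - 1
    }
    columns <- columns + 1L
  }
  list(score = S[n + 1, m + 1], matches = matches, columns = columns,
       gaps = gaps, identity = 100 * matches / columns)
}

# Brute-force per-position pileup counting.
naive_pileup <- function(aln, len) {
  depth <- integer(len); s5 <- integer(len); e3 <- integer(len)
  for (r in seq_len(nrow(aln))) {
    s <- aln$start[r]; e <- aln$end[r]
    for (p in seq.int(s + 1L, e)) depth[p] <- depth[p] + 1L
    s5[s + 1L] <- s5[s + 1L] + 1L
    e3[e] <- e3[e] + 1L
  }
  list(depth = depth, starts5 = s5, ends3 = e3)
}

# Naive six-frame ORF enumeration by explicit codon walking.
naive_orfs <- function(seq, min_aa) {
  gcode <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  rows <- list()
  emit <- function(s0, s1, strand, frame, s_oriented) {
    # s0/s1: 1-based nt bounds (closed) on the oriented strand
    codon_starts <- seq.int(s0, s1 - 2L, by = 3L)
    codons <- substring(s_oriented, codon_starts, codon_starts + 2L)
    coding <- codons[!(codons %in% stops)]
    aa <- gcode[coding]; aa[is.na(aa)] <- "X"
    start0 <- s0 - 1L; end0 <- s1
    if (strand == "-") { tmp <- L - end0; end0 <- L - start0; start0 <- tmp }
    data.frame(start = start0, end = end0, strand = strand, frame = frame,
               protein = paste(aa, collapse = ""), stringsAsFactors = FALSE)
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else fldsvirome::revcomp(seq)
    for (frame in 0:2) {
      pos <- frame + 1L
      atg <- NA_integer_
      while (pos + 2L <= L) {
        codon <- substr(s, pos, pos + 2L)
        if (codon %in% stops) {
          if (!is.na(atg) && (pos - atg) / 3L >= min_aa)
            rows[[length(rows) + 1L]] <- emit(atg, pos + 2L, strand, frame, s)
          atg <- NA_integer_
        } else if (is.na(atg) && codon == "ATG") {
          atg <- pos
        }
        pos <- pos + 3L
      }
      if (!is.na(atg) && (pos - atg) / 3L >= min_aa)
        rows[[length(rows) + 1L]] <- emit(atg, pos - 1L, strand, frame, s)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Order an ORF table canonically so set comparison is well-defined.
orf_canon <- function(o) {
  o <- o[order(o$start, o$end, o$strand), c("start", "end", "strand",
                                            "frame", "protein")]
  rownames(o) <- NULL
  o
}

# Independent re-execution of the greedy centroid rule from an all-pairs
# identity matrix computed with the textbook aligner.
naive_greedy_otus <- function(records, min_len, thr_frac) {
  records <- records[nchar(records) > min_len]
  if (!length(records)) return(list())
  records <- records[order(-nchar(records), names(records))]
  ids <- names(records)
  idm <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids))
    if (i != j) idm[i, j] <- nw_oracle(records[[i]], records[[j]])$identity
  centroids <- character(0); members <- list()
  for (id in ids) {
    hit <- NA_integer_
    for (ci in seq_along(centroids)) {
      if (id == centroids[ci] ||
          idm[id, centroids[ci]] >= 100 * thr_frac) { hit <- ci; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      members[[length(centroids)]] <- id
    } else if (id != centroids[hit]) {
      members[[hit]] <- c(members[[hit]], id)
    }
  }
  lapply(seq_along(centroids), function(i)
    list(centroid_id = centroids[i], member_ids = members[[i]]))
}

# Random nucleotide string helper.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Substitute exactly n positions of a sequence (any base change).
substitute_n <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Small two-genome simulation used across module tests.
small_sim_params <- function(seed = 1L, ...) {
  args <- list(n_genomes = 2L, segments_per_genome = c(1L, 2L),
               segment_len_range = c(1500L, 1800L),
               ssrna_genome_weights = c(0.7, 0.3),
               n_reads_ssrna = 5000L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

# A minimal read_class_counts object for rule tests.
make_counts <- function(total, rrna, viral) {
  structure(list(total = total, rrna = rrna,
                 viral_per_target = viral,
                 other = total - rrna - sum(viral),
                 per_read = data.frame()), class = "read_class_counts")
}

# A minimal genome_set object.
make_set <- function(members, set_id = "set01") {
  structure(list(set_id = set_id, members = members,
                 consensus_terminal5 = "", consensus_terminal3 = "",
                 gc_range = c(min = NA, max = NA), total_length = 0L,
                 min_member_cov = NA_real_,
                 flags = c(gc_ok = NA, orf_ok = NA, dominant = NA)),
            class = "genome_set")
}
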