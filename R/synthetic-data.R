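#' Simulation parameters for FLDS-like synthetic data
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions this package is built around: five viral genomes with
#' segment counts 1, 2, 2, 10 and 10 (one multipartite genome of 10 segments
#' mirrors the largest known segmented RNA virus genomes); a dsRNA-seq
#' library in which viral reads make up ~20% and residual rRNA ~30% of reads;
#' and a conventional ssRNA-seq library dominated by rRNA (~80%) with rare
#' viral reads (~0.5%). Reads whose fragment end coincides with a true
#' segment terminus are over-represented by `terminal_end_boost`, emulating
#' the terminal read-end pile-up that FLDS library construction produces.
#'
#' @param n_genomes number of viral genomes.
#' @param segments_per_genome integer vector (length `n_genomes`) of segment
#'   counts, each >= 1.
#' @param segment_len_range min/max segment length in nt (min >= 600).
#' @param terminal_len length in nt of the conserved 5'/3' terminal motifs
#'   shared by all segments of one genome (>= 10).
#' @param dsrna_viral_frac,dsrna_rrna_frac expected read-class fractions in
#'   the dsRNA-seq library (remainder = other host transcripts).
#' @param ssrna_rrna_frac,ssrna_viral_frac expected read-class fractions in
#'   the ssRNA-seq library.
#' @param read_len simulated read length in nt (single-end).
#' @param coverage_mean target mean per-base viral coverage (x) in the
#'   dsRNA-seq library; determines the library size unless `n_reads_dsrna`
#'   is given.
#' @param terminal_end_boost multiplicative weight on the two terminal
#'   fragment-start positions relative to interior positions.
#' @param subst_error_rate per-base substitution error probability.
#' @param n_reads_dsrna optional explicit dsRNA-seq library size (overrides
#'   the coverage-derived size).
#' @param n_reads_ssrna ssRNA-seq library size.
#' @param ssrna_genome_weights relative viral-read weights per genome in the
#'   ssRNA-seq library (length `n_genomes`); the defaults put three genomes
#'   above and two below the 0.1%-of-non-rRNA host-assignment threshold.
#' @param ssu_weights named weights of the background SSU rRNA references
#'   (a dominant host SSU and one minor eukaryote SSU).
#' @param n_host_mrna,mrna_len_range background host transcript roster.
#' @param seed integer seed; fully determines all generator output.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_genomes = 5L,
                       segments_per_genome = c(1L, 2L, 2L, 10L, 10L),
                       segment_len_range = c(1500L, 3000L),
                       terminal_len = 20L,
                       dsrna_viral_frac = 0.20, dsrna_rrna_frac = 0.30,
                       ssrna_rrna_frac = 0.80, ssrna_viral_frac = 0.005,
                       read_len = 150L,
                       coverage_mean = 100,
                       terminal_end_boost = 50,
                       subst_error_rate = 0,
                       n_reads_dsrna = NULL,
                       n_reads_ssrna = 100000L,
                       ssrna_genome_weights = c(0.54, 0.2, 0.2, 0.03, 0.03),
                       ssu_weights = c(ssu_host = 0.92, ssu_minor = 0.08),
                       n_host_mrna = 20L,
                       mrna_len_range = c(800L, 2000L),
                       seed = 1L) {
  p <- list(n_genomes = as.integer(n_genomes),
            segments_per_genome = as.integer(segments_per_genome),
            segment_len_range = as.integer(segment_len_range),
            terminal_len = as.integer(terminal_len),
            dsrna_viral_frac = dsrna_viral_frac,
            dsrna_rrna_frac = dsrna_rrna_frac,
            ssrna_rrna_frac = ssrna_rrna_frac,
            ssrna_viral_frac = ssrna_viral_frac,
            read_len = as.integer(read_len),
            coverage_mean = coverage_mean,
            terminal_end_boost = terminal_end_boost,
            subst_error_rate = subst_error_rate,
            n_reads_dsrna = if (is.null(n_reads_dsrna)) NULL else as.integer(n_reads_dsrna),
            n_reads_ssrna = as.integer(n_reads_ssrna),
            ssrna_genome_weights = ssrna_genome_weights,
            ssu_weights = ssu_weights,
            n_host_mrna = as.integer(n_host_mrna),
            mrna_len_range = as.integer(mrna_len_range),
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fr <- c(p$dsrna_viral_frac, p$dsrna_rrna_frac,
          p$ssrna_rrna_frac, p$ssrna_viral_frac)
  if (any(fr < 0 | fr > 1))
    stop("read-class fractions must lie in [0, 1]")
  if (p$dsrna_viral_frac + p$dsrna_rrna_frac > 1)
    stop("dsRNA-seq class fractions sum to > 1")
  if (p$ssrna_rrna_frac + p$ssrna_viral_frac > 1)
    stop("ssRNA-seq class fractions sum to > 1")
  if (length(p$segments_per_genome) != p$n_genomes)
    stop("segments_per_genome must have length n_genomes")
  if (any(p$segments_per_genome < 1L))
    stop("segment counts must be >= 1")
  if (p$terminal_len < 10L)
    stop("terminal_len must be >= 10 nt")
  if (p$segment_len_range[1] < 600L)
    stop("minimum segment length must be >= 600 nt")
  if (2L * p$terminal_len >= p$segment_len_range[1])
    stop("terminal motifs do not fit in the shortest segment")
  if (p$read_len < 30L) stop("read_len too short")
  if (p$terminal_end_boost < 1) stop("terminal_end_boost must be >= 1")
  if (p$subst_error_rate < 0 || p$subst_error_rate >= 1)
    stop("subst_error_rate must lie in [0, 1)")
  if (length(p$ssrna_genome_weights) != p$n_genomes)
    stop("ssrna_genome_weights must have length n_genomes")
  if (!is.finite(p$seed)) stop("seed is required")
  invisible(p)
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
# Decoy (non-RdRp) proteins are drawn from an aspartate-free alphabet so that
# the RdRp motif grammar ([GSA]DD etc.) structurally cannot match them.
AA_NO_D <- setdiff(AA20, "D")

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_protein <- function(len, alphabet = AA_NO_D) {
  paste(c("M", sample(alphabet, len - 1L, replace = TRUE)), collapse = "")
}

# An RdRp-like protein carrying the canonical polymerase motifs:
# motif A (D-x(4,5)-D), motif B (G-x(2,3)-T) and motif C (GDD), in order and
# within the scanner's spacing window. Outside the motifs the protein is
# aspartate-free, so the first [GSA]DD occurrence is the planted motif C.
random_rdrp_protein <- function(len = 350L) {
  ax <- sample(4:5, 1L)
  bx <- sample(2:3, 1L)
  part1 <- sample(AA_NO_D, 119L, replace = TRUE)
  motif_a <- c("D", sample(AA_NO_D, ax, replace = TRUE), "D")
  part2 <- sample(AA_NO_D, 40L, replace = TRUE)
  motif_b <- c("G", sample(AA_NO_D, bx, replace = TRUE), "T")
  part3 <- sample(AA_NO_D, 40L, replace = TRUE)
  motif_c <- c("G", "D", "D")
  tail_len <- max(10L, len - (120L + length(motif_a) + 40L +
                               length(motif_b) + 40L + 3L))
  part4 <- sample(AA_NO_D, tail_len, replace = TRUE)
  paste(c("M", part1, motif_a, part2, motif_b, part3, motif_c, part4),
        collapse = "")
}

# Reverse-translate a protein with sampled synonymous codons, then tune
# synonymous choices toward the target GC so even ORF-dominated segments can
# satisfy the within-genome GC constraint. Ends with a TAA stop codon.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

codon_gc_counts <- function() {
  cods <- names(Biostrings::GENETIC_CODE)
  stats::setNames(vapply(strsplit(cods, ""), function(x)
    sum(x %in% c("G", "C")), numeric(1)), cods)
}

protein_to_dna <- function(protein, gc_target = 0.5) {
  tab <- codon_table()
  cgc <- codon_gc_counts()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(x) {
    opts <- tab[[x]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  total_nt <- 3L * length(codons) + 3L
  target_gc_nt <- round(gc_target * total_nt)
  cur <- sum(cgc[codons])
  for (i in sample.int(length(codons))) {
    if (abs(cur - target_gc_nt) <= 1) break
    opts <- tab[[aa[i]]]
    if (length(opts) == 1L) next
    pick <- if (cur < target_gc_nt) opts[which.max(cgc[opts])] else
      opts[which.min(cgc[opts])]
    cur <- cur - cgc[[codons[i]]] + cgc[[pick]]
    codons[i] <- pick
  }
  paste(c(codons, "TAA"), collapse = "")
}

# Assemble one segment: [terminal5][gap L ... TAA][ORF][gap R][terminal3].
# The in-frame TAA directly upstream of the ORF guarantees that the ORF
# finder reports the planted start codon, and the gap GC content compensates
# the ~50% GC of the coding part so whole-segment GC lands on gc_target.
assemble_segment <- function(len, term5, term3, orf_dna, gc_target) {
  t5 <- nchar(term5); t3 <- nchar(term3); on <- nchar(orf_dna)
  core <- len - t5 - t3
  stopifnot(core >= on + 23L)
  gapL_len <- sample(seq.int(3L, core - on - 20L), 1L)
  gapR_len <- core - on - gapL_len
  gap_gc <- (gc_target * core - 0.5 * on) / (gapL_len + gapR_len)
  gap_gc <- min(max(gap_gc, 0.2), 0.8)
  gapL <- random_dna(gapL_len, gap_gc)
  substr(gapL, gapL_len - 2L, gapL_len) <- "TAA"
  seq <- paste0(term5, gapL, orf_dna, random_dna(gapR_len, gap_gc), term3)
  orf_start <- t5 + gapL_len          # 0-based
  list(sequence = seq, orf_start = orf_start, orf_end = orf_start + on)
}

# Sample one segment until (a) whole-segment GC is within 2 points of the
# genome's target (so within-genome GC spread is < 5 points by construction)
# and (b) the ORF finder reports exactly the planted ORF at min_aa = 100.
build_segment <- function(len, term5, term3, protein, gc_target,
                          max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    orf_dna <- protein_to_dna(protein, gc_target)
    seg <- assemble_segment(len, term5, term3, orf_dna, gc_target)
    if (abs(gc_percent(seg$sequence) - 100 * gc_target) > 2) next
    found <- find_orfs(seg$sequence, min_aa = 100L)
    if (nrow(found) == 1L && found$start == seg$orf_start &&
        found$end == seg$orf_end && found$strand == "+") {
      seg$protein <- protein
      return(seg)
    }
  }
  stop("failed to assemble a clean segment in ", max_tries, " tries")
}

# Conserved terminal motifs for each genome, mutually dissimilar so that
# terminal-similarity grouping can never bridge two genomes.
draw_terminal_motifs <- function(n, len, max_identity = 70, max_tries = 500L) {
  for (tr in seq_len(max_tries)) {
    mot <- replicate(n, random_dna(len, 0.5))
    ok <- TRUE
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (nw_identity(mot[i], mot[j]) > max_identity) { ok <- FALSE; break }
      }
    }
    if (ok) return(mot)
  }
  stop("could not draw mutually dissimilar terminal motifs")
}

#' Generate ground-truthed segmented viral genomes
#'
#' Builds `n_genomes` synthetic RNA virus genomes. All segments of one genome
#' start with the same conserved 5' terminal motif and end with the same 3'
#' motif; motifs are mutually dissimilar between genomes (pairwise global
#' alignment identity <= 70%). Segment GC stays within 2 points of the
#' genome's GC target, so within-genome spread is below the 5-point
#' validation rule. The first segment of each genome carries a single ORF
#' encoding an RdRp-like protein with the canonical A/B/C polymerase motifs;
#' every other segment carries one ORF encoding a decoy protein that cannot
#' match the motif grammar. The ORF roster found by [find_orfs()] on each
#' segment equals the planted roster exactly.
#'
#' @param params a [sim_params()] object.
#' @return list of `truth_genome` objects, each with elements `genome_id`,
#'   `segments` (named character), `terminal5`, `terminal3`, `has_rdrp`,
#'   `rdrp_segment`, `gc_target` and `orfs` (data.frame with the planted ORF
#'   coordinates, type and protein).
#' @export
generate_genomes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    t5 <- draw_terminal_motifs(params$n_genomes, params$terminal_len)
    t3 <- draw_terminal_motifs(params$n_genomes, params$terminal_len)
    genomes <- vector("list", params$n_genomes)
    for (g in seq_len(params$n_genomes)) {
      gid <- sprintf("virus%02d", g)
      nseg <- params$segments_per_genome[g]
      gc_target <- stats::runif(1, 0.45, 0.55)
      proteins <- character(nseg)
      proteins[1] <- random_rdrp_protein()
      if (nseg > 1L) for (j in seq.int(2L, nseg)) {
        repeat {
          cand <- random_protein(sample(150:250, 1L))
          sims <- vapply(proteins[seq_len(j - 1L)],
                         function(p) protein_similarity(cand, p), numeric(1))
          if (all(sims <= 45)) { proteins[j] <- cand; break }
        }
      }
      segs <- character(nseg); orfs <- vector("list", nseg)
      for (j in seq_len(nseg)) {
        need <- 3L * nchar(proteins[j]) + 3L + 2L * params$terminal_len + 60L
        len <- max(sample(seq.int(params$segment_len_range[1],
                                  params$segment_len_range[2]), 1L), need)
        built <- build_segment(len, t5[g], t3[g], proteins[j], gc_target)
        sid <- sprintf("%s_s%02d", gid, j)
        segs[j] <- built$sequence
        names(segs)[j] <- sid
        orfs[[j]] <- data.frame(
          seq_id = sid, start = built$orf_start, end = built$orf_end,
          strand = "+", type = if (j == 1L) "rdrp" else "other",
          protein = built$protein, stringsAsFactors = FALSE)
      }
      genomes[[g]] <- structure(list(
        genome_id = gid, segments = segs,
        terminal5 = t5[g], terminal3 = t3[g],
        has_rdrp = TRUE, rdrp_segment = names(segs)[1],
        gc_target = gc_target,
        orfs = do.call(rbind, orfs)), class = "truth_genome")
    }
    genomes
  })
}

#' @export
print.truth_genome <- function(x, ...) {
  cat(sprintf("truth_genome %s: %d segment(s), %d nt total, GC target %.1f%%\n",
              x$genome_id, length(x$segments), sum(nchar(x$segments)),
              100 * x$gc_target))
  invisible(x)
}

#' Flatten a genome roster
#'
#' @param genomes list of `truth_genome` objects.
#' @return `all_segments()`: named character vector of all segment sequences;
#'   `truth_membership()`: named character vector mapping segment id to
#'   genome id.
#' @export
all_segments <- function(genomes) {
  do.call(c, lapply(genomes, function(g) g$segments))
}

#' @rdname all_segments
#' @export
truth_membership <- function(genomes) {
  out <- unlist(lapply(genomes, function(g)
    stats::setNames(rep(g$genome_id, length(g$segments)), names(g$segments))))
  out
}

#' Generate the cellular background
#'
#' One dominant host SSU rRNA, one minor eukaryote SSU rRNA, and a roster of
#' host mRNAs, mirroring a holobiont transcriptome in which the host SSU
#' dominates the rRNA pool.
#'
#' @param params a [sim_params()] object.
#' @return list with named character vectors `rrna` and `mrna`.
#' @export
generate_background <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed + 7L, {
    rrna <- c(ssu_host = random_dna(1800L, 0.5),
              ssu_minor = random_dna(1800L, 0.5))
    names(rrna) <- names(params$ssu_weights)
    lens <- sample(seq.int(params$mrna_len_range[1], params$mrna_len_range[2]),
                   params$n_host_mrna, replace = TRUE)
    mrna <- vapply(lens, random_dna, character(1), gc = 0.5)
    names(mrna) <- sprintf("mrna_%02d", seq_along(mrna))
    list(rrna = rrna, mrna = mrna)
  })
}

# Apply i.i.d. substitution errors at the given per-base rate.
apply_subst_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Sample reads from one reference set. For viral segments the two terminal
# fragment-start positions (alignment start 0 and alignment end = segment
# length) carry `boost` times the weight of an interior position.
sample_reads_from <- function(refs, n, read_len, boost = 1) {
  if (n == 0L || length(refs) == 0L) {
    return(data.table::data.table(ref_id = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  seq = character()))
  }
  lens <- nchar(refs)
  stopifnot(all(lens >= read_len))
  pick <- sample.int(length(refs), n, replace = TRUE, prob = lens)
  out <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    ni <- sum(pick == i)
    if (ni == 0L) next
    npos <- lens[i] - read_len + 1L
    w <- rep(1, npos)
    if (boost > 1 && npos >= 2L) w[c(1L, npos)] <- boost
    starts <- sample.int(npos, ni, replace = TRUE, prob = w) - 1L
    strand <- sample(c("+", "-"), ni, replace = TRUE)
    sq <- substring(refs[i], starts + 1L, starts + read_len)
    neg <- strand == "-"
    if (any(neg)) sq[neg] <- revcomp(sq[neg])
    out[[i]] <- data.table::data.table(
      ref_id = names(refs)[i], start = starts, end = starts + read_len,
      strand = strand, seq = sq)
  }
  data.table::rbindlist(out)
}

simulate_library <- function(genomes, background, params, library, n_reads) {
  segs <- all_segments(genomes)
  membership <- truth_membership(genomes)
  if (library == "dsrna") {
    vf <- params$dsrna_viral_frac; rf <- params$dsrna_rrna_frac
    boost <- params$terminal_end_boost
    prefix <- "ds"
  } else {
    vf <- params$ssrna_viral_frac; rf <- params$ssrna_rrna_frac
    boost <- 1
    prefix <- "ss"
  }
  if (rf > 0 && length(background$rrna) == 0L)
    stop("nonzero rRNA fraction but background contains no rRNA")
  if (1 - vf - rf > 0 && length(background$mrna) == 0L)
    stop("nonzero background fraction but background contains no transcripts")
  counts <- as.vector(stats::rmultinom(1L, n_reads, c(vf, rf, 1 - vf - rf)))
  # viral reads
  if (library == "dsrna") {
    viral <- sample_reads_from(segs, counts[1], params$read_len, boost)
  } else {
    wg <- params$ssrna_genome_weights / sum(params$ssrna_genome_weights)
    per_genome <- as.vector(stats::rmultinom(1L, counts[1], wg))
    viral <- data.table::rbindlist(lapply(seq_along(genomes), function(g)
      sample_reads_from(genomes[[g]]$segments, per_genome[g],
                        params$read_len, 1)))
  }
  viral[, class := if (.N) "viral" else character(0)]
  # rRNA reads, split by SSU weights
  ssu_w <- params$ssu_weights / sum(params$ssu_weights)
  per_ssu <- as.vector(stats::rmultinom(1L, counts[2], ssu_w))
  rrna <- data.table::rbindlist(lapply(seq_along(background$rrna), function(i)
    sample_reads_from(background$rrna[i], per_ssu[i], params$read_len)))
  if (nrow(rrna)) rrna[, class := "rrna"]
  other <- sample_reads_from(background$mrna, counts[3], params$read_len)
  if (nrow(other)) other[, class := "other"]
  truth <- data.table::rbindlist(list(viral, rrna, other), fill = TRUE)
  truth[, read_id := sprintf("%s_%07d", prefix, seq_len(.N))]
  truth[, genome_id := membership[ref_id]]
  reads <- apply_subst_errors(truth$seq, params$subst_error_rate)
  names(reads) <- truth$read_id
  truth_df <- as.data.frame(truth[, .(read_id, ref_id, start, end, strand,
                                      class, genome_id)])
  list(reads = reads, truth = truth_df, params = params)
}

#' Simulate an FLDS dsRNA-seq read library
#'
#' Draws single-end reads whose class composition (viral / rRNA / other) is a
#' multinomial at the `sim_params` fractions. Viral read positions are
#' uniform over a segment except that the two terminal fragment-start
#' positions (truth alignment start 0, and end = segment length) carry
#' `terminal_end_boost` times the interior weight, emulating the FLDS
#' terminal read-end pile-up. Library size is
#' `total viral nt * coverage_mean / read_len / dsrna_viral_frac` unless
#' `n_reads_dsrna` is set.
#'
#' @param genomes output of [generate_genomes()].
#' @param background output of [generate_background()].
#' @param params a [sim_params()] object.
#' @return list with `reads` (named character vector, FASTQ-writable with
#'   [write_fastq()]), `truth` (one row per read: `read_id`, `ref_id`,
#'   0-based half-open `start`/`end`, `strand`, `class`, `genome_id`) and the
#'   echoed `params`.
#' @export
simulate_dsrna_reads <- function(genomes, background, params) {
  stopifnot(inherits(params, "sim_params"), length(genomes) > 0L)
  n <- params$n_reads_dsrna
  if (is.null(n)) {
    if (params$dsrna_viral_frac <= 0)
      stop("n_reads_dsrna must be given when dsrna_viral_frac is 0")
    total_nt <- sum(nchar(all_segments(genomes)))
    n <- as.integer(ceiling(total_nt * params$coverage_mean /
                              params$read_len / params$dsrna_viral_frac))
  }
  with_seed(params$seed + 1L,
            simulate_library(genomes, background, params, "dsrna", n))
}

#' Simulate a conventional ssRNA-seq read library
#'
#' As [simulate_dsrna_reads()] but with the ssRNA-seq class fractions
#' (rRNA-dominated, rare viral reads), viral reads allocated across genomes
#' by `ssrna_genome_weights`, and no terminal boost.
#'
#' @inheritParams simulate_dsrna_reads
#' @return same shape as [simulate_dsrna_reads()].
#' @export
simulate_ssrna_reads <- function(genomes, background, params) {
  stopifnot(inherits(params, "sim_params"), length(genomes) > 0L)
  with_seed(params$seed + 2L,
            simulate_library(genomes, background, params, "ssrna",
                             params$n_reads_ssrna))
}

#' Mutate a genome by a fixed number of SNVs
#'
#' Introduces exactly `n_snv` single-nucleotide substitutions at uniformly
#' sampled positions outside the conserved terminal motifs (so mutation never
#' disturbs terminal-similarity grouping), of which exactly `ti_count` are
#' transitions (A<->G or C<->T) and the rest transversions.
#'
#' @param genome a `truth_genome`.
#' @param n_snv total number of variant positions.
#' @param ti_count number of transitions among them (`<= n_snv`).
#' @param seed integer seed.
#' @return the mutated `truth_genome`, with a `mutations` element
#'   (data.frame: `segment_id`, 0-based `position`, `ref`, `alt`, `klass`).
#' @export
mutate_genome <- function(genome, n_snv, ti_count, seed = 1L) {
  stopifnot(inherits(genome, "truth_genome"),
            n_snv >= 0L, ti_count >= 0L, ti_count <= n_snv)
  tlen5 <- nchar(genome$terminal5); tlen3 <- nchar(genome$terminal3)
  lens <- nchar(genome$segments)
  pool <- data.table::rbindlist(lapply(seq_along(lens), function(i) {
    data.table::data.table(segment_id = names(lens)[i],
                           position = seq.int(tlen5, lens[i] - tlen3 - 1L))
  }))
  if (n_snv > nrow(pool))
    stop("n_snv exceeds the number of mutable (non-terminal) positions")
  ti_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  with_seed(seed, {
    picked <- pool[sample.int(nrow(pool), n_snv)]
    data.table::setorder(picked, segment_id, position)
    is_ti <- rep(FALSE, n_snv)
    if (n_snv > 0L) is_ti[sample.int(n_snv, ti_count)] <- TRUE
    segs <- genome$segments
    muts <- vector("list", n_snv)
    for (i in seq_len(nrow(picked))) {
      sid <- picked$segment_id[i]; pos <- picked$position[i]
      ref <- substr(segs[[sid]], pos + 1L, pos + 1L)
      alt <- if (is_ti[i]) ti_map[[ref]] else sample(tv_map[[ref]], 1L)
      substr(segs[[sid]], pos + 1L, pos + 1L) <- alt
      muts[[i]] <- data.frame(segment_id = sid, position = pos,
                              ref = ref, alt = alt,
                              klass = if (is_ti[i]) "transition" else "transversion",
                              stringsAsFactors = FALSE)
    }
    out <- genome
    out$segments <- segs
    out$mutations <- if (n_snv > 0L) do.call(rbind, muts) else
      data.frame(segment_id = character(), position = integer(),
                 ref = character(), alt = character(), klass = character(),
                 stringsAsFactors = FALSE)
    out
  })
}

#' Truncated decoy contigs
#'
#' Produces, for each genome, a copy of its first segment with `trim` nt
#' removed from one end (alternating 3'/5' across genomes). Decoys emulate
#' incompletely assembled contigs: they can never acquire a read pile-up at
#' the truncated end and so must never be classified full-length.
#'
#' @param genomes list of `truth_genome` objects.
#' @param trim nt removed from the truncated end.
#' @return named character vector of decoy contigs; names carry a
#'   `_trunc5`/`_trunc3` suffix on the source segment id.
#' @export
make_decoy_contigs <- function(genomes, trim = 50L) {
  out <- character(0)
  for (g in seq_along(genomes)) {
    seg <- genomes[[g]]$segments[1]
    len <- nchar(seg)
    if (g %% 2L == 1L) {
      out[paste0(names(seg), "_trunc3")] <- substr(seg[[1]], 1L, len - trim)
    } else {
      out[paste0(names(seg), "_trunc5")] <- substr(seg[[1]], trim + 1L, len)
    }
  }
  out
}
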