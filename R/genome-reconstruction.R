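#' Terminal-sequence similarity between two segments
#'
#' Percent identity of the two 5' windows and of the two 3' windows,
#' computed by global alignment of the window sequences (both sequences
#' oriented 5'->3'; no cross-end comparison). The window length and the
#' grouping threshold are interpretations exposed in [flds_config()] — the
#' underlying procedure defines grouping only as "similarity of terminal
#' sequences".
#'
#' @param a,b segment sequences (single strings).
#' @param window window length in nt.
#' @return named numeric vector `c(end5, end3)` of percent identities.
#' @export
terminal_similarity <- function(a, b, window = 20L) {
  a <- as.character(a); b <- as.character(b)
  if (window > nchar(a) || window > nchar(b))
    stop("window exceeds sequence length")
  c(end5 = nw_identity(substr(a, 1L, window), substr(b, 1L, window)),
    end3 = nw_identity(substr(a, nchar(a) - window + 1L, nchar(a)),
                       substr(b, nchar(b) - window + 1L, nchar(b))))
}

#' Group full-length segments into putative genome sets
#'
#' Single-linkage clustering on the relation "both 5' and 3' terminal-window
#' identity at or above the grouping threshold". Single linkage matches the
#' transitive nature of the conserved-termini signal: every segment of one
#' genome shares the same terminal motifs. Every input segment lands in
#' exactly one set; singleton sets are allowed (monopartite genomes).
#'
#' @param sequences named character vector of full-length segment sequences.
#' @param config a [flds_config()].
#' @param coverage optional named numeric vector of per-segment mean
#'   coverages (used for `min_member_cov`).
#' @return list of `genome_set` objects: `set_id`, `members`,
#'   `consensus_terminal5`, `consensus_terminal3`, `gc_range`,
#'   `total_length`, `min_member_cov`, and validation `flags`.
#' @export
group_segments <- function(sequences, config = flds_config(),
                           coverage = NULL) {
  sequences <- as_seq_chr(sequences, "sequences")
  n <- length(sequences)
  if (n == 0L) return(list())
  ids <- names(sequences)
  w <- config$terminal_window
  thr <- 100 * config$terminal_identity
  edges <- NULL
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    keep <- logical(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      sim <- terminal_similarity(sequences[[i]], sequences[[j]], w)
      keep[p] <- sim[["end5"]] >= thr && sim[["end3"]] >= thr
    }
    edges <- pairs[, keep, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && ncol(edges))
    g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  # deterministic set order: size descending, then smallest member id
  sets <- split(seq_len(n), comp)
  first_id <- vapply(sets, function(ix) min(ids[ix]), character(1))
  ord <- order(-lengths(sets), first_id)
  sets <- sets[ord]
  lapply(seq_along(sets), function(k) {
    ix <- sets[[k]]
    mem <- sort(ids[ix])
    seqs <- sequences[mem]
    longest <- mem[which.max(nchar(seqs))]
    gcs <- gc_percent(seqs)
    cov <- if (is.null(coverage)) rep(NA_real_, length(mem)) else
      unname(coverage[mem])
    structure(list(
      set_id = sprintf("set%02d", k),
      members = mem,
      consensus_terminal5 = substr(sequences[[longest]], 1L, w),
      consensus_terminal3 = substr(sequences[[longest]],
                                   nchar(sequences[[longest]]) - w + 1L,
                                   nchar(sequences[[longest]])),
      gc_range = c(min = min(gcs), max = max(gcs)),
      total_length = sum(nchar(seqs)),
      min_member_cov = if (all(is.na(cov))) NA_real_ else min(cov, na.rm = TRUE),
      flags = c(gc_ok = NA, orf_ok = NA, dominant = NA)),
      class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set %s: %d member(s), %d nt, GC %.1f-%.1f%%\n",
              x$set_id, length(x$members), x$total_length,
              x$gc_range[["min"]], x$gc_range[["max"]]))
  invisible(x)
}

#' Validate a genome set
#'
#' Applies the two within-group consistency rules: the GC spread among
#' members must be below `gc_max_diff` percentage points, and no ORF may
#' show amino-acid identity above `orf_sim_max` percent to an ORF encoded by
#' a different member of the same set (a true multipartite genome does not
#' encode the same protein twice).
#'
#' @param set a `genome_set`.
#' @param sequences named character vector covering the set members.
#' @param orfs ORF table from [find_orfs()]/[find_orfs_all()] with columns
#'   `parent_id` and `protein` (may cover more sequences than the set).
#' @param config a [flds_config()].
#' @return the `genome_set` with `flags["gc_ok"]`, `flags["orf_ok"]` set and
#'   an `orf_offenders` data.frame of failing member pairs.
#' @export
validate_genome_set <- function(set, sequences, orfs,
                                config = flds_config()) {
  stopifnot(inherits(set, "genome_set"))
  sequences <- as_seq_chr(sequences, "sequences")
  seqs <- sequences[set$members]
  gcs <- gc_percent(seqs)
  set$gc_range <- c(min = min(gcs), max = max(gcs))
  set$flags[["gc_ok"]] <- (max(gcs) - min(gcs)) < config$gc_max_diff
  o <- orfs[orfs$parent_id %in% set$members, , drop = FALSE]
  offenders <- list()
  orf_ok <- TRUE
  if (nrow(o) > 1L) {
    for (i in seq_len(nrow(o) - 1L)) for (j in seq.int(i + 1L, nrow(o))) {
      if (o$parent_id[i] == o$parent_id[j]) next
      sim <- protein_similarity(o$protein[i], o$protein[j])
      if (sim > config$orf_sim_max) {
        orf_ok <- FALSE
        offenders[[length(offenders) + 1L]] <- data.frame(
          member_a = o$parent_id[i], member_b = o$parent_id[j],
          identity = sim, stringsAsFactors = FALSE)
      }
    }
  }
  set$flags[["orf_ok"]] <- orf_ok
  set$orf_offenders <- if (length(offenders)) do.call(rbind, offenders) else
    data.frame(member_a = character(), member_b = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  set
}

#' Resolve validation conflicts by ejecting members
#'
#' Iteratively removes the lowest-coverage member implicated in a GC or ORF
#' failure, re-validating after each ejection; ejected members become
#' singleton sets. A clean simulation never triggers this; it automates what
#' would otherwise be manual curation of conflicting groups.
#'
#' @param sets list of `genome_set` objects.
#' @param sequences named character vector covering all members.
#' @param orfs ORF table (see [validate_genome_set()]).
#' @param coverage named numeric vector of member coverages.
#' @param config a [flds_config()].
#' @return list of validated `genome_set` objects (possibly more sets than
#'   input, renumbered).
#' @export
resolve_genome_sets <- function(sets, sequences, orfs, coverage,
                                config = flds_config()) {
  out <- list()
  queue <- sets
  while (length(queue)) {
    s <- validate_genome_set(queue[[1]], sequences, orfs, config)
    queue <- queue[-1]
    if ((isTRUE(s$flags[["gc_ok"]]) && isTRUE(s$flags[["orf_ok"]])) ||
        length(s$members) == 1L) {
      out[[length(out) + 1L]] <- s
      next
    }
    # implicated members: ORF offenders if any, else the GC extremes
    imp <- unique(c(s$orf_offenders$member_a, s$orf_offenders$member_b))
    if (!length(imp)) {
      gcs <- gc_percent(sequences[s$members])
      imp <- s$members[c(which.min(gcs), which.max(gcs))]
    }
    eject <- imp[which.min(coverage[imp])]
    rest <- s; rest$members <- setdiff(s$members, eject)
    single <- s; single$members <- eject
    queue <- c(list(rest), queue, list(single))
  }
  lapply(seq_along(out), function(k) {
    s <- out[[k]]
    s$set_id <- sprintf("set%02d", k)
    seqs <- sequences[s$members]
    s$total_length <- sum(nchar(seqs))
    s$min_member_cov <- if (length(coverage)) min(coverage[s$members]) else NA_real_
    s
  })
}

#' Coverage dominance of genome sets
#'
#' Computes each RdRp-encoding record's share of the summed mean coverage
#' over all RdRp-encoding segments and contigs, aggregates shares per genome
#' set, and flags sets whose members all exceed the dominance threshold
#' (default > 1,000x).
#'
#' @param sets list of `genome_set` objects.
#' @param rdrp_coverage named numeric vector: mean coverage of every
#'   RdRp-encoding record (set members and unplaced contigs alike).
#' @param coverage named numeric vector of mean coverage for all set members
#'   (for the dominance flag).
#' @param config a [flds_config()].
#' @return list with `records` (data.frame `seq_id`, `mean_coverage`,
#'   `share` in percent, summing to 100) and `sets` (data.frame `set_id`,
#'   `share`, `dominant`).
#' @export
coverage_dominance <- function(sets, rdrp_coverage, coverage = rdrp_coverage,
                               config = flds_config()) {
  if (length(rdrp_coverage) == 0L)
    stop("no RdRp-encoding records: coverage share undefined")
  total <- sum(rdrp_coverage)
  records <- data.frame(seq_id = names(rdrp_coverage),
                        mean_coverage = unname(rdrp_coverage),
                        share = 100 * unname(rdrp_coverage) / total,
                        stringsAsFactors = FALSE)
  set_rows <- lapply(sets, function(s) {
    mem_rdrp <- intersect(s$members, names(rdrp_coverage))
    share <- sum(records$share[records$seq_id %in% mem_rdrp])
    mem_cov <- coverage[s$members]
    data.frame(set_id = s$set_id, share = share,
               dominant = all(!is.na(mem_cov)) && all(mem_cov > config$dominance_cov),
               stringsAsFactors = FALSE)
  })
  list(records = records, sets = do.call(rbind, set_rows))
}
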