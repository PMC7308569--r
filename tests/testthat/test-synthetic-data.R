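test_that("generated genomes satisfy the truth-genome invariants", {
  p <- small_sim_params(seed = 101)
  genomes <- generate_genomes(p)
  expect_length(genomes, 2L)
  all_ids <- unlist(lapply(genomes, function(g) names(g$segments)))
  expect_false(anyDuplicated(all_ids) > 0)
  for (g in genomes) {
    for (s in g$segments) {
      expect_identical(substr(s, 1, nchar(g$terminal5)), g$terminal5)
      expect_identical(substr(s, nchar(s) - nchar(g$terminal3) + 1, nchar(s)),
                       g$terminal3)
    }
    # GC within 5 percentage points of the genome target
    expect_true(all(abs(gc_percent(g$segments) - 100 * g$gc_target) < 5))
    # exactly one segment carries the RdRp ORF label
    expect_identical(sum(g$orfs$type == "rdrp"), 1L)
    expect_identical(g$orfs$seq_id[g$orfs$type == "rdrp"], g$rdrp_segment)
  }
  # terminal motifs are dissimilar between genomes (below grouping threshold)
  expect_lt(nw_align(genomes[[1]]$terminal5, genomes[[2]]$terminal5)$identity, 80)
  expect_lt(nw_align(genomes[[1]]$terminal3, genomes[[2]]$terminal3)$identity, 80)
})

test_that("the five-genome default roster yields 25 segments", {
  p <- sim_params(segment_len_range = c(1500L, 2200L), seed = 7)
  genomes <- generate_genomes(p)
  expect_length(genomes, 5L)
  expect_identical(unname(vapply(genomes, function(g) length(g$segments),
                                 integer(1))), c(1L, 2L, 2L, 10L, 10L))
  expect_length(all_segments(genomes), 25L)
})

test_that("a single-segment genome with 15-nt terminals is built as specified", {
  p <- sim_params(n_genomes = 1L, segments_per_genome = 1L,
                  terminal_len = 15L, segment_len_range = c(1500L, 1600L),
                  ssrna_genome_weights = 1, seed = 5)
  g <- generate_genomes(p)[[1]]
  expect_identical(nchar(g$terminal5), 15L)
  s <- g$segments[[1]]
  expect_identical(substr(s, 1, 15), g$terminal5)
  expect_identical(substr(s, nchar(s) - 14, nchar(s)), g$terminal3)
})

test_that("identical parameters reproduce byte-identical FASTA output", {
  p <- small_sim_params(seed = 33)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(all_segments(generate_genomes(p)), f1)
  write_fasta(all_segments(generate_genomes(p)), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("dsRNA-seq class fractions land within 3 binomial SD at n = 100,000", {
  p <- small_sim_params(seed = 51, n_reads_dsrna = 100000L)
  genomes <- generate_genomes(p)
  bg <- generate_background(p)
  ds <- simulate_dsrna_reads(genomes, bg, p)
  expect_identical(length(ds$reads), 100000L)
  nv <- sum(ds$truth$class == "viral")
  nr <- sum(ds$truth$class == "rrna")
  sd_v <- sqrt(1e5 * 0.2 * 0.8); sd_r <- sqrt(1e5 * 0.3 * 0.7)
  expect_lt(abs(nv - 20000), 3 * sd_v)
  expect_lt(abs(nr - 30000), 3 * sd_r)
})

test_that("ssRNA-seq rRNA fraction lands within 3 binomial SD and zero viral leaves no viral truth", {
  p <- small_sim_params(seed = 52, n_reads_ssrna = 100000L)
  genomes <- generate_genomes(p)
  bg <- generate_background(p)
  ss <- simulate_ssrna_reads(genomes, bg, p)
  nr <- sum(ss$truth$class == "rrna")
  expect_lt(abs(nr - 80000), 3 * sqrt(1e5 * 0.8 * 0.2))
  p0 <- small_sim_params(seed = 53, ssrna_viral_frac = 0,
                         n_reads_ssrna = 5000L)
  ss0 <- simulate_ssrna_reads(generate_genomes(p0), generate_background(p0), p0)
  expect_identical(sum(ss0$truth$class == "viral"), 0L)
})

test_that("terminal boost produces the >10-read pile-up at every segment terminus", {
  # boost 50 at 30x coverage; short reads keep the expected terminal count
  # (~ boost * coverage / read length) comfortably above the calling bar
  p <- small_sim_params(seed = 54, coverage_mean = 30, read_len = 50L,
                        segment_len_range = c(600L, 1000L))
  genomes <- generate_genomes(p)
  ds <- simulate_dsrna_reads(genomes, generate_background(p), p)
  tv <- ds$truth[ds$truth$class == "viral", ]
  for (sid in names(all_segments(genomes))) {
    n0 <- sum(tv$ref_id == sid & tv$start == 0)
    expect_gte(n0, 11L)
  }
})

test_that("error-free reads are exact substrings of their source on the recorded strand", {
  p <- small_sim_params(seed = 55, n_reads_dsrna = 500L)
  genomes <- generate_genomes(p)
  bg <- generate_background(p)
  ds <- simulate_dsrna_reads(genomes, bg, p)
  refs <- c(all_segments(genomes), bg$rrna, bg$mrna)
  tr <- ds$truth
  for (i in seq_len(nrow(tr))) {
    src <- substr(refs[[tr$ref_id[i]]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") src <- revcomp(src)
    expect_identical(unname(ds$reads[tr$read_id[i]]), src)
  }
})

test_that("every read appears exactly once in the truth table", {
  p <- small_sim_params(seed = 56, n_reads_dsrna = 3000L)
  genomes <- generate_genomes(p)
  ds <- simulate_dsrna_reads(genomes, generate_background(p), p)
  expect_identical(sort(names(ds$reads)), sort(ds$truth$read_id))
  expect_false(anyDuplicated(ds$truth$read_id) > 0)
})

test_that("realized class counts are consistent with a multinomial draw across seeds", {
  p0 <- sim_params(n_genomes = 1L, segments_per_genome = 1L,
                   segment_len_range = c(1500L, 1600L),
                   ssrna_genome_weights = 1, seed = 1L,
                   n_reads_dsrna = 100000L)
  genomes <- generate_genomes(p0)
  bg <- generate_background(p0)
  probs <- c(0.2, 0.3, 0.5)
  for (seed in 1:20) {
    p <- p0; p$seed <- seed + 1000L
    ds <- simulate_dsrna_reads(genomes, bg, p)
    obs <- c(sum(ds$truth$class == "viral"), sum(ds$truth$class == "rrna"),
             sum(ds$truth$class == "other"))
    pv <- stats::chisq.test(obs, p = probs)$p.value
    expect_gt(pv, 0.001)
  }
})

test_that("mutate_genome introduces exactly the requested SNV spectrum", {
  p <- sim_params(n_genomes = 1L, segments_per_genome = 2L,
                  segment_len_range = c(1500L, 1600L),
                  ssrna_genome_weights = 1, seed = 61)
  g <- generate_genomes(p)[[1]]
  set.seed(62)
  cases <- rbind(c(0, 0), c(4, 0), c(54, 49), c(100, 100),
                 t(replicate(10, { n <- sample(0:100, 1); c(n, sample(0:n, 1)) })))
  for (r in seq_len(nrow(cases))) {
    n <- cases[r, 1]; ti <- cases[r, 2]
    mut <- mutate_genome(g, n, ti, seed = 1000 + r)
    expect_identical(nchar(mut$segments), nchar(g$segments))
    # naive position-by-position diff oracle
    ndiff <- 0L; nti <- 0L
    for (sid in names(g$segments)) {
      a <- strsplit(g$segments[[sid]], "")[[1]]
      b <- strsplit(mut$segments[[sid]], "")[[1]]
      d <- which(a != b)
      ndiff <- ndiff + length(d)
      nti <- nti + sum(paste0(a[d], b[d]) %in% c("AG", "GA", "CT", "TC"))
      # never inside the terminal motifs
      tl <- nchar(g$terminal5)
      expect_true(all(d > tl & d <= length(a) - tl))
    }
    expect_identical(ndiff, as.integer(n))
    expect_identical(nti, as.integer(ti))
    expect_identical(nrow(mut$mutations), as.integer(n))
  }
  expect_error(mutate_genome(g, sum(nchar(g$segments)), 0),
               "exceeds")
})

test_that("contradictory simulator parameters are rejected", {
  expect_error(sim_params(terminal_len = 9L), "terminal_len")
  expect_error(sim_params(segment_len_range = c(500L, 3000L)), "600")
  expect_error(sim_params(dsrna_viral_frac = 0.7, dsrna_rrna_frac = 0.5),
               "sum")
  expect_error(sim_params(segments_per_genome = c(1L, 2L)), "length")
})
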