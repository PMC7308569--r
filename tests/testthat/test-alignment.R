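test_that("clean simulated reads map back to their truth intervals", {
  p <- small_sim_params(seed = 201, n_reads_dsrna = 2000L)
  genomes <- generate_genomes(p)
  bg <- generate_background(p)
  ds <- simulate_dsrna_reads(genomes, bg, p)
  segs <- all_segments(genomes)
  aln <- map_reads(ds$reads, segs)
  tv <- ds$truth[ds$truth$class == "viral", ]
  m <- merge(tv, aln, by = "read_id", suffixes = c(".truth", ".got"))
  expect_identical(nrow(m), nrow(tv))   # every viral read mapped
  expect_true(all(m$ref_id.truth == m$ref_id.got))
  expect_true(all(m$start.truth == m$start.got))
  expect_true(all(m$end.truth == m$end.got))
  expect_true(all(m$strand.truth == m$strand.got))
  expect_true(all(aln$n_mismatches == 0L))
})

test_that("reads without a shared 21-mer stay unmapped; reverse-complement reads map on minus strand", {
  set.seed(202)
  ref <- c(refA = rand_dna(1000))
  # a random 100-mer almost surely shares no 21-mer with an unrelated ref
  stray <- c(r1 = rand_dna(100))
  expect_identical(nrow(map_reads(stray, ref)), 0L)
  fwd <- c(r2 = substr(ref[[1]], 101, 200))
  rc <- c(r3 = revcomp(substr(ref[[1]], 101, 200)))
  a_f <- map_reads(fwd, ref)
  a_r <- map_reads(rc, ref)
  expect_identical(a_f$strand, "+")
  expect_identical(a_r$strand, "-")
  expect_identical(a_r$start, 100L)
  expect_identical(a_r$end, 200L)
})

test_that("best-hit ties break to the lexicographically smallest reference", {
  set.seed(203)
  s <- rand_dna(400)
  refs <- c(beta = s, alfa = s)
  rd <- c(r = substr(s, 51, 150))
  a <- map_reads(rd, refs)
  expect_identical(a$ref_id, "alfa")
})

test_that("SAM round trip preserves all alignment fields", {
  set.seed(204)
  refs <- c(c1 = rand_dna(500), c2 = rand_dna(800))
  n <- 1000
  ref_id <- sample(names(refs), n, replace = TRUE)
  len <- sample(50:100, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(nchar(refs[[ref_id[i]]]) - len[i], 1) - 1L, integer(1))
  aln <- data.frame(read_id = sprintf("r%04d", seq_len(n)), ref_id = ref_id,
                    start = start, end = start + len,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    n_mismatches = sample(0:3, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".sam")
  write_sam(aln, refs, path)
  back <- read_sam(path)
  expect_equal(back, aln, ignore_attr = TRUE)
})

test_that("SAM coordinate and flag conventions are honoured", {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:ref1\tLN:300",
               "r1\t0\tref1\t1\t255\t100M\t*\t0\t0\t*\t*",
               "r2\t16\tref1\t11\t255\t5S90M\t*\t0\t0\t*\t*\tNM:i:2"),
             path)
  a <- read_sam(path)
  expect_identical(a$start[1], 0L)
  expect_identical(a$end[1], 100L)
  expect_identical(a$strand[1], "+")
  # soft clips do not move the terminal positions
  expect_identical(a$start[2], 10L)
  expect_identical(a$end[2], 100L)
  expect_identical(a$strand[2], "-")
  expect_identical(a$n_mismatches[2], 2L)
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:ref1\tLN:300",
               "r1\t0\trefX\t1\t255\t100M\t*\t0\t0\t*\t*"), bad)
  expect_error(read_sam(bad), "unknown reference")
})

test_that("pileup matches hand-checkable cases and conserves totals", {
  aln <- data.frame(read_id = c("a", "b", "c"), ref_id = "r",
                    start = 0L, end = 100L, strand = "+",
                    n_mismatches = 0L, stringsAsFactors = FALSE)
  pr <- pileup(aln, 150, "r")
  expect_identical(pr$depth[1:100], rep(3L, 100))
  expect_identical(pr$depth[101:150], rep(0L, 50))
  expect_identical(pr$starts5[1], 3L)
  expect_identical(pr$ends3[100], 3L)
  expect_equal(pr$mean_coverage, 300 / 150)
  empty <- pileup(aln[0, ], 50, "r")
  expect_identical(sum(empty$depth), 0L)
  expect_identical(empty$mean_coverage, 0)
})

test_that("pileup equals brute-force counting on random alignment sets", {
  set.seed(205)
  for (i in 1:25) {
    len <- sample(50:300, 1)
    n <- sample(1:80, 1)
    s <- sample(0:(len - 10), n, replace = TRUE)
    e <- pmin(len, s + sample(5:50, n, replace = TRUE))
    aln <- data.frame(read_id = sprintf("r%d", 1:n), ref_id = "x",
                      start = s, end = e, strand = "+", n_mismatches = 0L,
                      stringsAsFactors = FALSE)
    pr <- pileup(aln, len, "x")
    oracle <- naive_pileup(aln, len)
    expect_identical(pr$depth, oracle$depth)
    expect_identical(pr$starts5, oracle$starts5)
    expect_identical(pr$ends3, oracle$ends3)
    # conservation invariants
    expect_identical(sum(pr$depth), sum(e - s))
    expect_identical(sum(pr$starts5), n)
    expect_identical(sum(pr$ends3), n)
  }
})

test_that("pileup rejects foreign or out-of-range alignments", {
  aln <- data.frame(read_id = "a", ref_id = "other", start = 0L, end = 10L,
                    strand = "+", n_mismatches = 0L, stringsAsFactors = FALSE)
  expect_error(pileup(aln, 100, "r"), "other references")
  aln$ref_id <- "r"; aln$end <- 200L
  expect_error(pileup(aln, 100, "r"), "outside")
})
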