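test_that("terminal similarity is 100 within a genome and low between genomes", {
  p <- small_sim_params(seed = 401, terminal_len = 15L)
  genomes <- generate_genomes(p)
  expect_identical(unname(terminal_similarity("ACGTACGTACGTACGTACGT",
                                              "ACGTACGTACGTACGTACGT")),
                   c(100, 100))
  within <- terminal_similarity(genomes[[2]]$segments[[1]],
                                genomes[[2]]$segments[[2]], window = 15L)
  expect_identical(unname(within), c(100, 100))
  between <- terminal_similarity(genomes[[1]]$segments[[1]],
                                 genomes[[2]]$segments[[1]], window = 15L)
  expect_true(any(between < 80))
  expect_error(terminal_similarity("ACGT", "ACGT", window = 10L), "window")
})

test_that("segments group into their genomes; degenerate thresholds split everything", {
  p <- small_sim_params(seed = 402)
  genomes <- generate_genomes(p)
  segs <- all_segments(genomes)
  sets <- group_segments(segs, flds_config())
  expect_length(sets, 2L)
  expect_identical(sort(vapply(sets, function(s) length(s$members), integer(1))),
                   c(1L, 2L))
  truth <- truth_membership(genomes)
  for (s in sets)
    expect_identical(length(unique(truth[s$members])), 1L)
  # single segment -> singleton set
  one <- group_segments(segs[1], flds_config())
  expect_length(one, 1L)
  expect_identical(one[[1]]$members, names(segs)[1])
  # threshold above 100% -> all singletons
  allsingle <- group_segments(segs, flds_config(terminal_identity = 1.01))
  expect_length(allsingle, length(segs))
})

test_that("grouping is a partition and refines under stricter thresholds", {
  for (seed in c(403, 404, 405)) {
    p <- small_sim_params(seed = seed)
    segs <- all_segments(generate_genomes(p))
    loose <- group_segments(segs, flds_config(terminal_identity = 0.6))
    strict <- group_segments(segs, flds_config(terminal_identity = 0.95))
    for (sets in list(loose, strict)) {
      members <- unlist(lapply(sets, `[[`, "members"))
      expect_identical(sort(members), sort(names(segs)))   # no overlap/omission
    }
    # refinement: every strict set is inside one loose set
    loose_of <- unlist(lapply(loose, function(s)
      stats::setNames(rep(s$set_id, length(s$members)), s$members)))
    for (s in strict)
      expect_identical(length(unique(loose_of[s$members])), 1L)
  }
})

test_that("GC validation applies the strict <5 point spread rule", {
  gcseq <- function(gc_frac, len = 1000L) {
    ngc <- round(len * gc_frac)
    paste0(strrep("G", ngc), strrep("A", len - ngc))
  }
  seqs <- c(m1 = gcseq(0.450), m2 = gcseq(0.499))
  orfs <- data.frame(parent_id = character(), protein = character())
  s <- validate_genome_set(make_set(c("m1", "m2")), seqs, orfs)
  expect_true(s$flags[["gc_ok"]])
  seqs2 <- c(m1 = gcseq(0.450), m2 = gcseq(0.500))
  s2 <- validate_genome_set(make_set(c("m1", "m2")), seqs2, orfs)
  expect_false(s2$flags[["gc_ok"]])   # spread of exactly 5.0 fails
})

test_that("identical ORFs on two members fail the non-redundancy rule", {
  set.seed(406)
  seqs <- c(m1 = rand_dna(1000), m2 = rand_dna(1000))
  prot <- paste(sample(c("M", AA <- LETTERS[1:20]), 120, TRUE), collapse = "")
  orfs <- data.frame(parent_id = c("m1", "m2"), protein = c(prot, prot),
                     stringsAsFactors = FALSE)
  s <- validate_genome_set(make_set(c("m1", "m2")), seqs, orfs)
  expect_false(s$flags[["orf_ok"]])
  expect_identical(nrow(s$orf_offenders), 1L)
})

test_that("validation conflicts are resolved by ejecting the lowest-coverage member", {
  set.seed(407)
  seqs <- c(m1 = rand_dna(1000), m2 = rand_dna(1000), m3 = rand_dna(1000))
  prot <- paste(sample(LETTERS[1:20], 150, TRUE), collapse = "")
  orfs <- data.frame(parent_id = c("m1", "m3"), protein = c(prot, prot),
                     stringsAsFactors = FALSE)
  cov <- c(m1 = 500, m2 = 400, m3 = 50)
  out <- resolve_genome_sets(list(make_set(c("m1", "m2", "m3"))),
                             seqs, orfs, cov)
  sizes <- vapply(out, function(s) length(s$members), integer(1))
  expect_identical(sort(sizes), c(1L, 2L))
  ejected <- out[[which(sizes == 1L)]]$members
  expect_identical(ejected, "m3")
  expect_true(all(vapply(out, function(s)
    isTRUE(s$flags[["orf_ok"]]), logical(1))))
})

test_that("coverage dominance reports shares that sum to 100", {
  one <- coverage_dominance(list(), c(contig1 = 1839))
  expect_equal(one$records$share, 100)
  s <- make_set("m1")
  s$members <- "m1"
  res <- coverage_dominance(list(s), c(m1 = 1839), c(m1 = 1839))
  expect_equal(res$sets$share, 100)
  expect_true(res$sets$dominant)
  # five dominant sets vs background of equal total coverage -> 50% combined
  sets <- lapply(1:5, function(i) {
    x <- make_set(paste0("v", i), sprintf("set%02d", i)); x
  })
  cov <- c(stats::setNames(rep(2000, 5), paste0("v", 1:5)),
           stats::setNames(rep(1000, 10), paste0("bg", 1:10)))
  res5 <- coverage_dominance(sets, cov, cov)
  expect_equal(sum(res5$sets$share), 50)
  expect_equal(sum(res5$records$share), 100, tolerance = 1e-9)
  expect_error(coverage_dominance(list(), numeric(0)), "undefined")
})

test_that("grouping recovers truth membership with ARI 1 across seeds", {
  for (seed in 501:505) {
    p <- small_sim_params(seed = seed)
    genomes <- generate_genomes(p)
    segs <- all_segments(genomes)
    sets <- group_segments(segs, flds_config())
    got <- unlist(lapply(sets, function(s)
      stats::setNames(rep(s$set_id, length(s$members)), s$members)))
    truth <- truth_membership(genomes)
    expect_equal(mclust::adjustedRandIndex(got[names(truth)], truth), 1)
  }
})
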