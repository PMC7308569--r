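test_that("ORF finding handles hand-checkable and strand-symmetric cases", {
  o <- find_orfs("ATGAAATAA", min_aa = 2L)
  expect_identical(nrow(o), 1L)
  expect_identical(o$protein, "MK")
  expect_identical(o$start, 0L)
  expect_identical(o$end, 9L)
  expect_identical(o$strand, "+")
  # same ORF recovered from the reverse complement on the minus strand
  set.seed(601)
  cds <- paste0("ATG", paste(sample(c("GCT", "AAA", "TGG", "CTG"), 120, TRUE),
                             collapse = ""), "TAA")
  seq <- paste0(rand_dna(50), cds, rand_dna(50))
  fwd <- find_orfs(seq, min_aa = 50L)
  rev <- find_orfs(revcomp(seq), min_aa = 50L)
  expect_true(any(fwd$strand == "+" & fwd$protein %in% rev$protein))
  expect_identical(sort(fwd$protein), sort(rev$protein))
  expect_identical(sort(rev$strand), sort(chartr("+-", "-+", fwd$strand)))
  expect_error(find_orfs("ATGQQQ"), "non-ACGTN")
})

test_that("ORF finder equals the naive six-frame enumeration on random sequences", {
  set.seed(602)
  for (i in 1:30) {
    seq <- rand_dna(sample(300:1200, 1))
    min_aa <- sample(c(5L, 10L, 20L), 1)
    got <- orf_canon(find_orfs(seq, min_aa))
    exp <- orf_canon(naive_orfs(seq, min_aa))
    expect_identical(got, exp)
  }
  # one larger instance
  seq <- rand_dna(10000)
  expect_identical(orf_canon(find_orfs(seq, 25L)),
                   orf_canon(naive_orfs(seq, 25L)))
})

test_that("RdRp motif scanning requires GDD plus a corroborating upstream motif", {
  prot <- withr::with_seed(603, fldsvirome:::random_rdrp_protein())
  hit <- scan_rdrp_motifs(prot)
  expect_false(is.null(hit))
  expect_identical(hit$motif_c_seq, "GDD")
  expect_true(hit$motif_a_found || hit$motif_b_found)
  # no motifs at all
  expect_null(scan_rdrp_motifs(strrep("A", 200)))
  # GDD without any corroborating upstream motif
  lone <- paste0(strrep("A", 150), "GDD", strrep("A", 60))
  expect_null(scan_rdrp_motifs(lone))
  # too short
  expect_null(scan_rdrp_motifs(strrep("AGDDA", 10)))
})

test_that("motif scan separates labeled RdRp and decoy ORFs on generated genomes", {
  p <- small_sim_params(seed = 604)
  genomes <- generate_genomes(p)
  for (g in genomes) {
    for (i in seq_len(nrow(g$orfs))) {
      hit <- scan_rdrp_motifs(g$orfs$protein[i])
      if (g$orfs$type[i] == "rdrp") expect_false(is.null(hit))
      else expect_null(hit)
    }
  }
})

test_that("protein identity matches hand cases and the DP oracle", {
  expect_equal(protein_similarity("MKVLW", "MKVLW"), 100)
  expect_equal(protein_similarity("MKL", "MQL"), 100 * 2 / 3, tolerance = 1e-12)
  set.seed(605)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:30) {
    a <- paste(sample(aas, sample(10:60, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(10:60, 1), TRUE), collapse = "")
    expect_identical(protein_similarity(a, b), nw_oracle(a, b)$identity)
  }
  expect_error(protein_similarity("", "MK"), "nonempty")
})

test_that("OTU clustering applies the 90% identity and >1.5 kb rules", {
  set.seed(606)
  base <- rand_dna(2000)
  cfg <- flds_config()
  # identical pair -> one OTU with two members
  one <- cluster_rdrp_otus(c(a = base, b = base), cfg)
  expect_length(one, 1L)
  expect_identical(sort(one[[1]]$member_ids), c("a", "b"))
  # 89% identity pair -> two OTUs
  div <- substitute_n(base, 220)   # 11% substitutions, no indels
  two <- cluster_rdrp_otus(c(a = base, b = div), cfg)
  expect_length(two, 2L)
  # 95% identity pair -> one OTU
  near <- substitute_n(base, 100)
  onem <- cluster_rdrp_otus(c(a = base, b = near), cfg)
  expect_length(onem, 1L)
  # length filter: records at or below 1.5 kb are dropped
  short <- cluster_rdrp_otus(c(a = base, s = rand_dna(1500)), cfg)
  expect_identical(unname(unlist(lapply(short, `[[`, "member_ids"))), "a")
})

test_that("greedy OTU clustering equals an independent re-execution and keeps centroids apart", {
  set.seed(607)
  cfg <- flds_config(otu_min_len = 50L)
  for (i in 1:8) {
    # families of mutated copies around a few founders, short for the oracle
    founders <- replicate(sample(2:4, 1), rand_dna(sample(60:90, 1)))
    recs <- unlist(lapply(seq_along(founders), function(f) {
      n <- sample(1:4, 1)
      sapply(seq_len(n), function(j)
        substitute_n(founders[f], sample(0:6, 1)))
    }))
    names(recs) <- sprintf("r%02d", seq_along(recs))
    got <- cluster_rdrp_otus(recs, cfg)
    exp <- naive_greedy_otus(recs, cfg$otu_min_len, cfg$otu_identity)
    expect_identical(lapply(got, `[[`, "centroid_id"),
                     lapply(exp, `[[`, "centroid_id"))
    expect_identical(lapply(got, function(o) sort(o$member_ids)),
                     lapply(exp, function(o) sort(o$member_ids)))
    # centroid property: pairwise identity below the threshold
    cent <- vapply(got, `[[`, character(1), "centroid_id")
    if (length(cent) > 1) {
      for (x in seq_len(length(cent) - 1)) for (y in seq.int(x + 1, length(cent)))
        expect_lt(nw_align(recs[[cent[x]]], recs[[cent[y]]])$identity,
                  100 * cfg$otu_identity)
    }
    # membership: every member reaches the threshold against its centroid
    for (o in got) for (mid in setdiff(o$member_ids, o$centroid_id))
      expect_gte(nw_align(recs[[mid]], recs[[o$centroid_id]])$identity,
                 100 * cfg$otu_identity)
  }
})
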