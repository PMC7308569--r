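---
title: "Methods: reconstructing segmented RNA virus genomes from dsRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing segmented RNA virus genomes from dsRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional metatranscriptome sequencing (ssRNA-seq) detects RNA viruses but
rarely recovers complete genomes: cDNA synthesis loses the literal 5' and 3'
termini of each genome segment, and without terminal sequences the segments
of a multipartite virus cannot be tied together. Sequencing the long
double-stranded RNA fraction of a sample (the dsRNA virome: dsRNA virus
genomes plus replicative intermediates of ssRNA viruses) with a
terminus-preserving protocol (FLDS: fragmented and primer-ligated dsRNA
sequencing) changes both points. Viral reads are strongly enriched, and
because true genome ends survive library construction, reads pile up
exactly at segment termini. That pile-up signature supports two inferences
this package automates:

1. **Full-length segment calling.** A contig position supported by more
   than 10 read ends is a terminal end; a contig with termini called at
   both ends is a full-length potential genome segment.
2. **Genome-set reconstruction.** Segments of one multipartite virus share
   conserved 5' and 3' terminal sequences. Grouping full-length segments by
   terminal similarity reassembles multi-segment genomes, validated by GC
   homogeneity and ORF non-redundancy within each group.

Around this core the package implements the standard companion analyses:
RdRp (RNA-dependent RNA polymerase) signature-motif detection, greedy
centroid OTU clustering of RdRp sequences at 90% nucleotide identity,
abundance-based host assignment from a companion ssRNA-seq library, and a
transition/transversion summary of SNVs between two consensus versions of
the same genome.

## The synthetic study system

Every stage is testable offline because the package ships a ground-truthed
generator (`sim_params()`, `generate_genomes()`, `simulate_dsrna_reads()`,
`simulate_ssrna_reads()`, `mutate_genome()`) that emulates the statistical
structure the analysis relies on. The defaults are the study conditions the
rest of the package is exercised under:

* **Genome roster.** Five viral genomes with segment counts 1, 2, 2, 10
  and 10 — a monopartite picorna-like genome, two bipartite genomes, and
  two 10-segment reo-like genomes (the largest known RNA virus genomes are
  10-segment, ~35 kb). Segment lengths are drawn from 1.5–3 kb.
* **Terminal motifs.** Every segment of a genome starts with the same
  20-nt 5' motif and ends with the same 20-nt 3' motif. Motifs of
  different genomes are rejection-sampled to pairwise global-alignment
  identity <= 70%, below the 80% grouping threshold, so terminal grouping
  can never bridge genomes.
* **GC structure.** Each genome draws a GC target in 45–55%; segments are
  rejection-sampled to within 2 points of the target (synonymous-codon
  choices in ORFs are tuned toward the target), so within-genome GC spread
  is below the 5-point validation rule by construction.
* **ORF content.** The first segment of each genome carries one ORF
  encoding an RdRp-like protein with the canonical A (`D-x(4,5)-D`),
  B (`G-x(2,3)-T`) and C (`GDD`) polymerase motifs in order. Every other
  segment carries one decoy ORF. Decoy proteins are drawn from an
  aspartate-free alphabet, so the motif grammar structurally cannot match
  them: the scanner's sensitivity-1 / false-positive-0 property on labeled
  ORFs is a designed feature of the truth labels, not an empirical claim
  about real proteins. Assembled segments are rejection-sampled until
  `find_orfs()` reports exactly the planted ORFs, which keeps the truth
  roster exact.
* **Read-class fractions.** dsRNA-seq reads are ~20% viral and ~30%
  residual rRNA; ssRNA-seq reads are ~80% rRNA with ~0.5% viral reads.
  Realized counts are a single multinomial draw per library.
* **Terminal pile-up.** Viral read start positions are uniform over a
  segment except that the two terminal fragment-start positions (alignment
  start 0, and alignment end = segment length) carry
  `terminal_end_boost` (default 50) times the interior weight. The
  protocol's terminal enrichment has no published generative model, so the
  boost is a free simulator parameter, not an estimate. The expected
  number of reads sharing a terminal start is approximately
  `boost * coverage / read_len`; the package defaults
  (`coverage_mean = 100`, `read_len = 150`) put that expectation near 34,
  comfortably above the 11-read calling bar, which is the calibration the
  end-to-end recovery checks run at.
* **Background.** One dominant host SSU rRNA (92% of rRNA reads), one
  minor eukaryote SSU (8%), and 20 random host mRNAs. This mirrors the
  host-dominated SSU profile of a holobiont without real taxa.
* **Mutated versions.** `mutate_genome(g, n, t)` plants exactly `n` SNVs
  with exactly `t` transitions, uniformly outside the terminal motifs (so
  mutation never disturbs grouping), and records the manifest used as the
  variant-calling oracle.

What the generator deliberately does **not** model: platform error
profiles, indels, chimeras, adapters, paired-end structure, base-quality
variation, related viral genomes with partially similar termini, the
secondary-structure biases that carry rRNA into real dsRNA fractions, and
assembly itself (the pipeline starts from contigs). Passing tests therefore demonstrate the correctness
of the decision rules and their implementations under the stated
conditions, not robustness to every artifact of real libraries.

## Decision rules and their boundary semantics

All numeric rules live in `flds_config()`:

| rule | default | reading |
|---|---|---|
| contig screen | >= 500 bp and >= 3x mean coverage | "at least", boundary kept |
| terminal call | >= 11 reads at the exact end | "> 10 reads", strict |
| terminal tolerance | W = 0 | optional window for trimmed assemblies |
| grouping | both-end window identity >= 80%, window 20 nt | interpretation (see below) |
| GC validation | spread < 5 points | strict: a spread of exactly 5 fails |
| ORF redundancy | identity > 50% fails | strict |
| OTU clustering | identity >= 90%, length > 1.5 kb | "< 90%" means distinct |
| dominance | all members > 1,000x | strict |
| host assignment | > 0.1% of non-rRNA reads | strict: exactly 0.1% is not assigned |

"Mean coverage" is the mean per-base depth over the full contig length, and
an alignment's terminal positions are its 5'-most and 3'-most reference
positions (soft clips in imported SAM do not move them).

## Design choices where the procedure is under-specified

* **Terminal similarity metric.** The published procedure groups "by
  similarity of terminal sequences" without a metric. This package uses
  percent identity from global alignment of 20-nt terminal windows with a
  >= 80% threshold at both ends, both sequences oriented 5'->3' and no
  cross-end matching. All three choices are exposed in `flds_config()` and
  should be treated as an interpretation.
* **Single linkage.** Conserved termini are a transitive signal (all
  segments of a genome share them), so grouping uses single-linkage
  components. Groups failing GC/ORF validation are repaired by iteratively
  ejecting the lowest-coverage implicated member
  (`resolve_genome_sets()`) — automating what would otherwise be manual
  curation.
* **ORF "similarity".** Whether the 50% ORF-redundancy rule means identity
  or matrix-based similarity is unstated; this package uses percent
  identity (matches / alignment columns) from global alignment with
  match +1, mismatch -1, gap -2.
* **RdRp motif grammar.** The signature residue set is not printed in the
  source procedure; the grammar here (`rdrp_motif_grammar()`) requires the
  catalytic `[GSA]DD` (motif C) plus at least one corroborating upstream
  motif (A: `D-x(4,5)-D`; B: `G-x(2,3)-T`) within 150 aa. It is a
  configurable approximation, isolated behind one function.
* **OTU identity.** Nucleotide identity for OTU clustering is
  matches / alignment columns on a global alignment — compatible with the
  centroid-clustering definition used by standard tools. Greedy order is
  length descending, id ascending: deterministic.
* **Host-assignment pooling.** The 0.1% rule is applied to per-virus
  pooled counts (all segments of a genome set together), since abundance is
  reported per virus, not per segment.
* **Mapping.** The built-in mapper (exact 21-mer seed, ungapped full-length
  extension, best hit by fewest mismatches with deterministic tie-breaking
  by reference id, then start, then strand) is sufficient for
  substitution-only synthetic reads; its identity threshold (0.95) is a
  configuration choice. Real-data users should import SAM from any
  external mapper — the original analysis used a proprietary assembler and
  mapper, both out of scope here.
* **rRNA classification.** A reference k-mer containment classifier
  (k = 21, containment >= 0.3, sampled with stride 5) stands in for
  dedicated rRNA filtering and SSU-reconstruction tools; it is
  deterministic and dependency-free at desk scale.
* **Variant calling.** Read-level quality-weighted variant detection is
  approximated by consensus-versus-consensus comparison: banded global
  alignment per segment with a strong gap penalty (-8), one variant per
  mismatch column, gaps excluded. The strong penalty prevents dense
  substitution clusters from re-aligning as spurious gaps; transitions are
  A<->G and C<->T.

## Numerical and reproducibility notes

* All alignment is Needleman–Wunsch with linear gap penalty (compiled
  core), deterministic traceback preference diagonal > gap-in-second >
  gap-in-first. Identity is matches / alignment columns x 100.
* Coordinates are 0-based half-open internally; SAM (1-based) and GFF3 /
  VCF conversions happen only at the I/O boundary.
* Every source of randomness flows from the integer seed in `sim_params()`
  (library simulation and mutation use small fixed offsets of it), and
  `run_flds_pipeline()` is byte-deterministic: re-running with the same
  configuration reproduces identical output checksums, which the manifest
  records.
* Degenerate inputs fail loudly: contigs without profiles, alignments
  beyond reference bounds, zero non-rRNA reads (undefined host fraction),
  an empty RdRp record set (undefined dominance share), mismatched segment
  rosters in version comparison.

## Problem sizes

The shipped checks run at desk scale, chosen so the full suite and the
acceptance script complete comfortably on a single CPU: the default
simulation covers 25 segments (~57 kb of viral sequence) at 100x dsRNA
coverage (~190,000 dsRNA-seq reads) and 100,000 ssRNA-seq reads;
read-class statistics are checked at n = 100,000; oracle equivalences run
on 100 random instances per operation; end-to-end grouping recovery is
additionally exercised across repeated seeds on a two-genome roster. The
published counts from the original field study (hundreds of RdRp sequences
and OTUs from millions of reads) derive from raw-read assembly with a
proprietary assembler plus database searches, and are out of scope by
design.

## Known limitations

* The mapper is substitution-only and single-hit; repeat-rich or
  indel-containing real contigs need an external mapper.
* The motif grammar will miss genuinely divergent RdRps (no profile-HMM
  search) — by design, since database/profile searches are out of scope.
* Terminal calling at W = 0 assumes assemblers report exact termini; real
  assemblies may need the tolerance window.
* The k-mer classifier requires ~30% of a read's k-mers intact; reads with
  more than ~5% substitutions degrade below the containment threshold.
* Host assignment is an abundance heuristic: it flags likely infection of
  the sampled organism, not proof of host range.
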