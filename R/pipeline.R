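#' Configuration for a full pipeline run
#'
#' Bundles the simulator parameters, the analysis thresholds and the
#' run-level options of the synthetic happy path
#' (simulate -> map -> call termini -> reconstruct -> annotate ->
#' host-assign -> variants).
#'
#' @param sim a [sim_params()] object.
#' @param pipeline a [flds_config()] object.
#' @param include_decoys add truncated decoy contigs to the contig set.
#' @param snv_n,snv_ti SNVs (and transitions among them) introduced into the
#'   mutated version of the largest genome for the variant stage.
#' @return object of class `flds_run_config`.
#' @export
flds_run_config <- function(sim = sim_params(), pipeline = flds_config(),
                            include_decoys = TRUE,
                            snv_n = 54L, snv_ti = 49L) {
  stopifnot(inherits(sim, "sim_params"), inherits(pipeline, "flds_config"))
  structure(list(sim = sim, pipeline = pipeline,
                 include_decoys = isTRUE(include_decoys),
                 snv_n = as.integer(snv_n), snv_ti = as.integer(snv_ti)),
            class = "flds_run_config")
}

#' @rdname flds_run_config
#' @param path path to a YAML file with optional blocks `sim`, `pipeline`
#'   and top-level `include_decoys`, `snv_n`, `snv_ti`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  flds_run_config(
    sim = do.call(sim_params, if (is.null(y$sim)) list() else y$sim),
    pipeline = do.call(flds_config,
                       if (is.null(y$pipeline)) list() else y$pipeline),
    include_decoys = if (is.null(y$include_decoys)) TRUE else y$include_decoys,
    snv_n = if (is.null(y$snv_n)) 54L else y$snv_n,
    snv_ti = if (is.null(y$snv_ti)) 49L else y$snv_ti)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic FLDS virome pipeline
#'
#' Executes every stage end-to-end on synthetic data and writes all stage
#' outputs plus a JSON run manifest to `out_dir`. Identical configurations
#' (including the seed) reproduce byte-identical outputs.
#'
#' @param config a [flds_run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with all in-memory stage results (`genomes`,
#'   `truth`, `alignments`, `records`, `sets`, `orfs`, `rdrp_hits`, `otus`,
#'   `dominance`, `ssrna_counts`, `hosts`, `ssu`, `variants`, `titv`,
#'   `manifest`).
#' @export
run_flds_pipeline <- function(config = flds_run_config(), out_dir,
                              quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "flds_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  sp <- config$sim; cfg <- config$pipeline
  counts <- list()

  say("stage simulate: genomes and read libraries")
  genomes <- stage("simulate", generate_genomes(sp))
  background <- stage("simulate", generate_background(sp))
  ds <- stage("simulate", simulate_dsrna_reads(genomes, background, sp))
  ss <- stage("simulate", simulate_ssrna_reads(genomes, background, sp))
  segs <- all_segments(genomes)
  contigs <- segs
  if (config$include_decoys) contigs <- c(contigs, make_decoy_contigs(genomes))
  write_fasta(segs, file.path(out_dir, "genomes.fasta"))
  write_fasta(c(background$rrna, background$mrna),
              file.path(out_dir, "background.fasta"))
  write_fastq(ds$reads, file.path(out_dir, "dsrna.fastq"))
  write_fastq(ss$reads, file.path(out_dir, "ssrna.fastq"))
  write_tsv(ds$truth, file.path(out_dir, "dsrna_truth.tsv"))
  write_tsv(ss$truth, file.path(out_dir, "ssrna_truth.tsv"))
  counts$dsrna_reads <- length(ds$reads)
  counts$ssrna_reads <- length(ss$reads)
  counts$contigs <- length(contigs)

  say("stage map: ", length(ds$reads), " dsRNA-seq reads vs ",
      length(contigs), " contigs")
  aln <- stage("map", {
    if (length(ds$reads) == 0L) stop("empty read set")
    map_reads(ds$reads, contigs, min_identity = cfg$min_identity,
              k = cfg$kmer_k)
  })
  write_sam(aln, contigs, file.path(out_dir, "dsrna.sam"))
  counts$mapped_reads <- nrow(aln)

  say("stage call-termini: screening ", length(contigs), " contigs")
  profiles <- stage("call-termini", pileup_all(aln, contigs))
  records <- stage("call-termini", screen_contigs(contigs, profiles, cfg))
  write_tsv(records, file.path(out_dir, "segments.tsv"))
  full <- records$seq_id[records$status == "full_length"]
  write_fasta(contigs[full], file.path(out_dir, "segments_full_length.fasta"))
  counts$segment_status <- as.list(summarize_segments(records))

  say("stage reconstruct: grouping ", length(full), " full-length segments")
  coverage <- stats::setNames(records$mean_coverage, records$seq_id)
  orfs <- stage("annotate", find_orfs_all(contigs[records$status != "discarded"],
                                          cfg$min_orf_aa))
  sets <- stage("reconstruct",
                group_segments(contigs[full], cfg, coverage = coverage))
  sets <- stage("reconstruct",
                resolve_genome_sets(sets, contigs, orfs, coverage, cfg))
  counts$genome_sets <- length(sets)

  say("stage annotate: RdRp motif scan and OTU clustering")
  rdrp_hits <- stage("annotate", {
    hits <- lapply(seq_len(nrow(orfs)), function(i)
      scan_rdrp_motifs(orfs$protein[i]))
    found <- !vapply(hits, is.null, logical(1))
    if (any(found)) data.frame(
      parent_id = orfs$parent_id[found],
      orf_start = orfs$start[found],
      motif_c_offset = vapply(hits[found], `[[`, integer(1), "motif_c_offset"),
      motif_c_seq = vapply(hits[found], `[[`, character(1), "motif_c_seq"),
      score = vapply(hits[found], `[[`, integer(1), "score"),
      stringsAsFactors = FALSE)
    else data.frame(parent_id = character(), orf_start = integer(),
                    motif_c_offset = integer(), motif_c_seq = character(),
                    score = integer(), stringsAsFactors = FALSE)
  })
  rdrp_ids <- unique(rdrp_hits$parent_id)
  otus <- stage("annotate", cluster_rdrp_otus(contigs[rdrp_ids], cfg))
  write_tsv(otu_table(otus), file.path(out_dir, "otus.tsv"))
  write_orfs_gff3(orfs, file.path(out_dir, "orfs.gff3"))
  counts$rdrp_records <- length(rdrp_ids)
  counts$otus <- length(otus)
  dominance <- stage("annotate", coverage_dominance(
    sets, coverage[rdrp_ids], coverage, cfg))

  say("stage host-assign: classifying ", length(ss$reads), " ssRNA-seq reads")
  target_of <- stage("host-assign", {
    m <- unlist(lapply(sets, function(s)
      stats::setNames(rep(s$set_id, length(s$members)), s$members)))
    m
  })
  ssrna_counts <- stage("host-assign",
                        classify_reads(ss$reads, background$rrna,
                                       contigs[names(target_of)],
                                       target_of = target_of, config = cfg))
  hosts <- stage("host-assign", host_assignment(ssrna_counts, cfg))
  ssu <- stage("host-assign", ssu_composition(ss$reads, background$rrna, cfg))
  write_tsv(hosts, file.path(out_dir, "abundance.tsv"))
  write_tsv(ssu, file.path(out_dir, "ssu_composition.tsv"))
  counts$hosts_assigned <- sum(hosts$assigned)

  say("stage variants: SNVs between genome versions")
  big <- genomes[[which.max(vapply(genomes, function(g)
    sum(nchar(g$segments)), numeric(1)))]]
  mutated <- stage("variants",
                   mutate_genome(big, config$snv_n, config$snv_ti,
                                 seed = sp$seed + 3L))
  variants <- stage("variants", call_snvs(align_versions(big, mutated)))
  titv <- titv_summary(variants)
  write_variants_vcf(variants, file.path(out_dir, "variants.vcf"))
  write_tsv(data.frame(n = titv$n, ti = titv$ti, tv = titv$tv,
                       ti_percent = titv$ti_percent),
            file.path(out_dir, "titv.tsv"))
  counts$snvs <- titv$n

  # genome-set table last (flags now final)
  set_table <- do.call(rbind, lapply(sets, function(s) data.frame(
    set_id = s$set_id, members = paste(s$members, collapse = ","),
    n_members = length(s$members), total_length = s$total_length,
    min_member_cov = s$min_member_cov,
    gc_ok = s$flags[["gc_ok"]], orf_ok = s$flags[["orf_ok"]],
    stringsAsFactors = FALSE)))
  set_table <- merge(set_table, dominance$sets, by = "set_id", sort = TRUE)
  write_tsv(set_table, file.path(out_dir, "genome_sets.tsv"))

  manifest <- list(
    tool = "fldsvirome",
    version = as.character(utils::packageVersion("fldsvirome")),
    seed = sp$seed,
    sim = unclass(sp),
    pipeline = unclass(cfg),
    include_decoys = config$include_decoys,
    snv_n = config$snv_n, snv_ti = config$snv_ti,
    stage_counts = counts,
    output_md5 = as.list(tools::md5sum(sort(list.files(
      out_dir, full.names = TRUE, pattern = "\\.(fasta|fastq|tsv|sam|gff3|vcf)$")))))
  names(manifest$output_md5) <- basename(names(manifest$output_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done: ", out_dir)
  invisible(list(genomes = genomes, background = background,
                 dsrna = ds, ssrna = ss, alignments = aln,
                 profiles = profiles, records = records, sets = sets,
                 orfs = orfs, rdrp_hits = rdrp_hits, otus = otus,
                 dominance = dominance, ssrna_counts = ssrna_counts,
                 hosts = hosts, ssu = ssu, variants = variants, titv = titv,
                 set_table = set_table, manifest = manifest))
}
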