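# End-to-end orchestration: simulate -> preprocess -> map -> junctions ->
# tails -> crosslink profiles -> enrichment summaries, emitting the
# declared text outputs (FASTA/FASTQ/GFF3/TSV/bedGraph/BED).

#' Run the full pipeline on a synthetic data set
#'
#' @param out_dir Output directory.
#' @param seed Master seed; all per-stage seeds derive from it.
#' @param genome_length,n_genes Synthetic world size.
#' @param n_molecules iCLIP molecules per library.
#' @param n_rnaseq RNA-Seq reads.
#' @param manifest_args Extra arguments for [ground_truth_manifest()].
#' @param min_reads,min_libraries circRNA candidate thresholds.
#' @return Invisible list with every intermediate object and output path.
#' @export
run_pipeline <- function(out_dir, seed = 1L, genome_length = 50000L,
                         n_genes = 40L, n_molecules = 1500L,
                         n_rnaseq = 20000L, manifest_args = list(),
                         min_reads = 10L, min_libraries = 3L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- build_genome(seed, length = genome_length)
  annotation <- build_annotation(genome, seed + 1L, n_genes = n_genes)
  manifest <- do.call(ground_truth_manifest,
                      c(list(genome = genome, annotation = annotation,
                             seed = seed + 2L), manifest_args))
  sim_paths <- write_simulation(out_dir, genome, annotation, manifest,
                                n_molecules = n_molecules,
                                n_rnaseq = n_rnaseq, seed = seed + 3L)
  libs <- names(manifest$barcode_table)

  # one pooled raw FASTQ, as delivered by a sequencer
  raw <- rbindlist(lapply(libs, function(l)
    read_fastq(file.path(out_dir, paste0(l, ".fq")), library = l)))
  pre <- preprocess_reads(raw, manifest$barcode_table)
  fwrite(pre$stats, file.path(out_dir, "preprocess_stats.tsv"), sep = "\t")

  index <- build_seed_index(genome)
  frag_index <- build_fragment_index(genome)
  per_lib <- list()
  junction_calls <- list()
  merged_aln <- list()
  for (lib in libs) {
    rr <- pre$libraries[[lib]]
    mp <- map_reads(genome, rr, index = index)
    cov <- build_coverage(mp$alignments, genome)
    write_bedgraph(cov, file.path(out_dir, paste0(lib, ".fwd.bedgraph")),
                   "+")
    write_bedgraph(cov, file.path(out_dir, paste0(lib, ".rev.bedgraph")),
                   "-")
    write_alignments_bed(mp$alignments,
                         file.path(out_dir, paste0(lib, ".bed")))
    write_fastq(mp$unmapped, file.path(out_dir,
                                       paste0(lib, ".unmapped.fq")))
    jc <- detect_junctions(mp$unmapped, genome, index = frag_index)
    junction_calls[[lib]] <- jc
    tl <- detect_tails(mp$unmapped, genome, exclude_ids = jc$read_id,
                       index = index)
    per_lib[[lib]] <- list(mapped = mp, coverage = cov, junctions = jc,
                           tails = tl)
    merged_aln[[lib]] <- mp$alignments
  }

  candidates <- aggregate_candidates(
    junction_calls, min_reads = min_reads, min_libraries = min_libraries,
    eligible_libraries = manifest$eligible_libraries)
  fwrite(candidates, file.path(out_dir, "circ_candidates.tsv"), sep = "\t")

  all_tails <- rbindlist(lapply(libs, function(l) {
    t <- per_lib[[l]]$tails
    if (nrow(t)) t[, library := l]
    t
  }), fill = TRUE)
  fwrite(all_tails, file.path(out_dir, "tails.tsv"), sep = "\t")
  tail_profile <- profile_tails(all_tails$tail)
  fwrite(tail_profile$position, file.path(out_dir, "tail_composition.tsv"),
         sep = "\t")

  # merged replicates for crosslink profiling (controls excluded)
  coip <- rbindlist(merged_aln[manifest$eligible_libraries])
  xl <- assign_crosslinks(coip, genome)
  write_bedgraph(xl, file.path(out_dir, "crosslinks.fwd.bedgraph"), "+")
  write_bedgraph(xl, file.path(out_dir, "crosslinks.rev.bedgraph"), "-")
  profiles <- list()
  for (bt in intersect(BIOTYPES, unique(annotation$biotype))) {
    for (ori in c("sense", "antisense")) {
      p <- decile_profile(xl, annotation[biotype == bt], ori, "percent")
      p[, `:=`(biotype = bt, orientation = ori)]
      profiles[[paste(bt, ori)]] <- p
    }
  }
  fwrite(rbindlist(profiles), file.path(out_dir, "decile_profiles.tsv"),
         sep = "\t")
  op_tab <- annotation[!is.na(operon_id), .(gene_id, operon_id)]
  if (nrow(op_tab)) {
    op <- operon_profile(xl, annotation, op_tab, "sense", "percent")
    fwrite(op, file.path(out_dir, "operon_decile_profile.tsv"), sep = "\t")
  }
  bp_start <- boundary_profile(xl, annotation, "start", 100L, 1L, "percent")
  bp_end <- boundary_profile(xl, annotation, "end", 100L, 1L, "percent")
  fwrite(bp_start, file.path(out_dir, "boundary_start.tsv"), sep = "\t")
  fwrite(bp_end, file.path(out_dir, "boundary_end.tsv"), sep = "\t")
  motif <- extract_motif_windows(xl, genome, top_k = 50L)
  if (length(motif))
    write_fasta(motif, file.path(out_dir, "motif_windows.fa"))

  # RNA-Seq coverage, enrichment summaries, genome content
  rna <- read_fastq(file.path(out_dir, "rnaseq.fq"), library = "RNASeq")
  rna_map <- map_reads(genome, rna, index = index)
  rna_cov <- build_coverage(rna_map$alignments, genome)
  write_bedgraph(rna_cov, file.path(out_dir, "rnaseq.fwd.bedgraph"), "+")
  write_bedgraph(rna_cov, file.path(out_dir, "rnaseq.rev.bedgraph"), "-")

  igrs <- igr_complement(annotation, genome)
  cds <- annotation[biotype == "protein_coding"]
  cds_regions <- cds[, .(replicon, start, end)]
  iclip_cov_merged <- build_coverage(coip, genome)
  ratio_cds <- coverage_ratio(iclip_cov_merged, rna_cov, cds_regions)
  ratio_igr <- coverage_ratio(iclip_cov_merged, rna_cov, igrs)
  content <- cds_content(gene_sequences(cds, genome))
  fwrite(content$table, file.path(out_dir, "cds_content.tsv"), sep = "\t")
  polya <- find_igr_polyA(igrs, genome)
  fwrite(polya, file.path(out_dir, "igr_polya.tsv"), sep = "\t")
  enrich <- rbindlist(lapply(seq_len(min(nrow(polya), 20L)), function(i) {
    ec <- call_enrichment(
      setNames(lapply(manifest$eligible_libraries,
                      function(l) per_lib[[l]]$coverage),
               manifest$eligible_libraries),
      rna_cov, polya[i], fold = 2)
    data.table(replicon = polya$replicon[i], start = polya$start[i],
               end = polya$end[i], strand = polya$strand[i],
               run_length = polya$run_length[i], enriched = ec$enriched)
  }))
  if (nrow(enrich))
    fwrite(enrich, file.path(out_dir, "igr_polya_enrichment.tsv"),
           sep = "\t")

  invisible(list(
    genome = genome, annotation = annotation, manifest = manifest,
    preprocess = pre, per_library = per_lib, candidates = candidates,
    tails = all_tails, tail_profile = tail_profile, crosslinks = xl,
    boundary_start = bp_start, boundary_end = bp_end,
    rnaseq_coverage = rna_cov, ratio_cds = ratio_cds,
    ratio_igr = ratio_igr, content = content, polya = polya,
    out_dir = out_dir, sim_paths = sim_paths))
}
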