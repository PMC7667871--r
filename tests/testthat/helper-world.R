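# Shared synthetic world, built once per test run. Sizes are kept small so
# the whole suite stays inside the runtime budget; seeds are fixed up
# front, not tuned.

library(data.table)

world <- local({
  genome <- build_genome(1, length = 20000)
  annotation <- build_annotation(genome, 2, n_genes = 20)
  manifest <- ground_truth_manifest(genome, annotation, seed = 3)
  list(genome = genome, annotation = annotation, manifest = manifest)
})

# plant crosslink counts directly into a track (crosslink-level stated
# world for the profiling properties; read-level simulation is exercised
# elsewhere)
plant_track <- function(genome, genes, n, decile_weights = rep(1, 10),
                        hotspot_offset = NULL, hotspot_fraction = 0) {
  track <- empty_track(genome)
  for (i in seq_len(n)) {
    g <- genes[sample.int(nrow(genes), 1)]
    L <- g$end - g$start
    if (!is.null(hotspot_offset) && runif(1) < hotspot_fraction) {
      p <- if (g$strand == "+") g$start + hotspot_offset
           else g$end - 1L - hotspot_offset
    } else {
      d <- sample.int(10, 1, prob = decile_weights)
      lo <- floor((d - 1) * L / 10)
      hi <- floor(d * L / 10) - 1
      local <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      p <- if (g$strand == "+") g$start + local else g$end - 1L - local
    }
    if (p < 0 || p >= length(track[[g$replicon]][["+"]])) next
    track[[g$replicon]][[g$strand]][p + 1L] <-
      track[[g$replicon]][[g$strand]][p + 1L] + 1L
  }
  track
}

# wrap plain per-base vectors into a one-replicon stranded track
vec_track <- function(fwd, rev = NULL, replicon = "chr1") {
  if (is.null(rev)) rev <- integer(length(fwd))
  setNames(list(list(`+` = fwd, `-` = rev)), replicon)
}

read_table <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                       library = NA_character_) {
  data.table(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
             mult = 1L, library = library)
}

flip_base <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]

track_sum <- function(track)
  sum(vapply(track, function(r) sum(r[["+"]]) + sum(r[["-"]]), numeric(1)))
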