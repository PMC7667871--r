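test_that("assign_crosslinks applies the truncation convention", {
  g <- c(chr = strrep("ACGT", 100))
  aln <- data.table(id = c("a", "b"), replicon = "chr",
                    start = c(100L, 100L), end = c(150L, 150L),
                    strand = c("+", "-"), nm = 0L, mult = 1L)
  tr <- assign_crosslinks(aln, g)
  expect_equal(tr$chr[["+"]][100], 1L)  # position 99, plus
  expect_equal(tr$chr[["-"]][151], 1L)  # position 150, minus
  # alignment at the replicon edge is dropped silently
  edge <- data.table(id = "e", replicon = "chr", start = 0L, end = 40L,
                     strand = "+", nm = 0L, mult = 1L)
  tr2 <- assign_crosslinks(edge, g)
  expect_equal(track_sum(tr2), 0)
})

test_that("called crosslink sites equal planted positions exactly", {
  w <- world
  man <- ground_truth_manifest(w$genome, w$annotation, seed = 3,
                               n_circles = 0, tail_fraction = 0)
  s <- simulate_iclip_library(w$genome, w$annotation, man, "Rrp4_1", 400,
                              seed = 101)
  pre <- preprocess_reads(s$reads, man$barcode_table)
  mp <- map_reads(w$genome, pre$libraries$Rrp4_1)
  tr <- assign_crosslinks(mp$alignments, w$genome)
  sites <- track_sites(tr)
  planted <- s$truth[, .N, by = .(replicon, pos = crosslink, strand)]
  m <- merge(sites, planted, by = c("replicon", "pos", "strand"),
             all = TRUE)
  expect_true(all(!is.na(m$count) & !is.na(m$N)))
  expect_equal(m$count, m$N)
})

test_that("decile assignment follows gene orientation for both strands", {
  g <- c(chr = strrep("ACGT", 50))
  genes <- data.table(gene_id = "g1", replicon = "chr", start = 0L,
                      end = 100L, strand = "+",
                      biotype = "protein_coding",
                      operon_id = NA_character_)
  tr <- empty_track(g)
  tr$chr[["+"]][6] <- 1L    # position 5 -> sense decile 1
  tr$chr[["-"]][96] <- 1L   # position 95 -> antisense decile 10
  sense <- decile_profile(tr, genes, "sense")
  anti <- decile_profile(tr, genes, "antisense")
  expect_equal(sense$count, c(1, rep(0, 9)))
  expect_equal(anti$count, c(rep(0, 9), 1))

  # minus-strand gene: decile 1 is at the genomic END
  genes_m <- copy(genes)[, strand := "-"]
  tr2 <- empty_track(g)
  tr2$chr[["-"]][96] <- 1L  # local offset 4 from the 5' end
  sense_m <- decile_profile(tr2, genes_m, "sense")
  expect_equal(sense_m$count, c(1, rep(0, 9)))
})

test_that("uniform placement passes chi-square and percent sums to 100", {
  w <- world
  genes <- w$annotation[biotype == "protein_coding"]
  set.seed(102)
  tr <- plant_track(w$genome, genes, 3000)
  p <- decile_profile(tr, genes, "sense", "percent")
  expect_equal(sum(p$percent), 100, tolerance = 1e-8)
  exp_cnt <- sum(p$count) / 10  # gene lengths are multiples of 10
  chisq <- sum((p$count - exp_cnt)^2 / exp_cnt)
  expect_gt(pchisq(chisq, df = 9, lower.tail = FALSE), 0.01)
})

test_that("conservation: decile counts equal in-gene crosslinks", {
  w <- world
  genes <- w$annotation[biotype == "protein_coding"]
  set.seed(103)
  tr <- plant_track(w$genome, genes, 1000)
  tot <- decile_profile(tr, genes, "sense")$count +
    decile_profile(tr, genes, "antisense")$count
  in_gene <- 0L
  for (i in seq_len(nrow(genes)))
    in_gene <- in_gene +
      sum(tr[[genes$replicon[i]]][["+"]][(genes$start[i] + 1):genes$end[i]]) +
      sum(tr[[genes$replicon[i]]][["-"]][(genes$start[i] + 1):genes$end[i]])
  expect_equal(sum(tot), in_gene)
})

test_that("operon units span member genes and reject discordant strands", {
  genes <- data.table(
    gene_id = c("a", "b", "c"), replicon = "chr",
    start = c(0L, 150L, 400L), end = c(100L, 250L, 500L),
    strand = c("+", "+", "+"), biotype = "protein_coding",
    operon_id = NA_character_)
  tab <- data.table(gene_id = c("a", "b"), operon_id = "op1")
  u <- operon_units(genes, tab)
  expect_equal(u$start, 0L)
  expect_equal(u$end, 250L)

  tab_single <- data.table(gene_id = "c", operon_id = "op2")
  u2 <- operon_units(genes, tab_single)
  expect_equal(u2$start, 400L)
  expect_equal(u2$end, 500L)

  genes_bad <- copy(genes)[gene_id == "b", strand := "-"]
  expect_error(operon_units(genes_bad, tab), "discordant")

  # crosslink in the intergenic gap inside the unit still counts
  g <- c(chr = strrep("ACGT", 150))
  tr <- empty_track(g)
  tr$chr[["+"]][130] <- 1L  # position 129, inside [0,250) unit, decile 6
  p <- operon_profile(tr, genes, tab, "sense")
  expect_equal(sum(p$count), 1)
})

test_that("boundary offsets follow transcript orientation, no zero", {
  g <- c(chr = strrep("ACGT", 500))
  genes <- data.table(gene_id = "g", replicon = "chr", start = 1000L,
                      end = 1100L, strand = "+",
                      biotype = "protein_coding",
                      operon_id = NA_character_)
  tr <- empty_track(g)
  tr$chr[["+"]][1000] <- 1L  # position 999 -> offset -1
  p <- boundary_profile(tr, genes, "start")
  expect_equal(p[count > 0, offset], -1L)
  expect_false(0L %in% p$offset)

  genes_m <- copy(genes)[, strand := "-"]
  tr2 <- empty_track(g)
  tr2$chr[["-"]][1101] <- 1L  # position 1100 -> offset -1 for a minus gene
  p2 <- boundary_profile(tr2, genes_m, "start")
  expect_equal(p2[count > 0, offset], -1L)

  # end anchor: last gene base -> -1, first downstream base -> +1
  tr3 <- empty_track(g)
  tr3$chr[["+"]][1100] <- 1L  # position 1099 (last base)
  tr3$chr[["+"]][1101] <- 2L  # position 1100 (first downstream)
  p3 <- boundary_profile(tr3, genes, "end")
  expect_equal(p3[offset == -1, count], 1)
  expect_equal(p3[offset == 1, count], 2)
})

test_that("binned boundary profile aggregates 10-nt bins", {
  g <- c(chr = strrep("ACGT", 500))
  genes <- data.table(gene_id = "g", replicon = "chr", start = 1000L,
                      end = 1100L, strand = "+",
                      biotype = "protein_coding",
                      operon_id = NA_character_)
  tr <- empty_track(g)
  tr$chr[["+"]][971:980] <- 1L  # offsets -30..-21
  p <- boundary_profile(tr, genes, "start", bin = 10L)
  expect_equal(nrow(p), 20L)
  expect_equal(p[offset == -30, count], 10)
  expect_equal(sum(p$count), 10)
})

test_that("extract_motif_windows returns 21-nt stranded windows", {
  g <- c(chr = paste(rep(c("A", "C", "G", "T"), 25), collapse = ""))
  tr <- empty_track(g)
  tr$chr[["+"]][51] <- 3L   # site at position 50
  tr$chr[["-"]][61] <- 1L   # site at position 60, minus
  tr$chr[["+"]][6] <- 5L    # site at position 5: too close to the edge
  win <- extract_motif_windows(tr, g, flank = 10L)
  expect_equal(length(win), 2L)
  expect_equal(unname(nchar(win)), c(21L, 21L))
  expect_equal(win[["chr:50:+"]], seq_extract(g, "chr", 40, 61))
  expect_equal(win[["chr:60:-"]], revcomp(seq_extract(g, "chr", 50, 71)))
  expect_false("chr:5:+" %in% names(win))
})
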