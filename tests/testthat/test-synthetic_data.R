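test_that("build_genome is deterministic with bounded composition", {
  g1 <- build_genome(1, length = 50000, gc = 0.5)
  g2 <- build_genome(1, length = 50000, gc = 0.5)
  expect_identical(g1, g2)
  gc <- sum(strsplit(g1[[1]], "")[[1]] %in% c("G", "C")) / 50000
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  expect_error(build_genome(1, length = 10), ">= 5000")
})

test_that("build_annotation packs valid genes with the requested mix", {
  g <- build_genome(5, length = 50000)
  ann <- build_annotation(g, 6, n_genes = 20,
                          biotype_mix = c(protein_coding = 0.7,
                                          tRNA = 0.2, rRNA = 0.05,
                                          other = 0.05))
  expect_equal(nrow(ann), 20)
  expect_true(all(ann$end - ann$start >= 100))
  expect_true(all(ann$end <= nchar(g[[1]])))
  # deterministic largest-remainder apportionment: tRNA 0.2 * 20 = 4
  expect_equal(sum(ann$biotype == "tRNA"), 4L)
  # designed convergent overlap is present
  ov <- FALSE
  setkey(ann, start)
  for (i in seq_len(nrow(ann) - 1))
    if (ann$end[i] > ann$start[i + 1] &&
        ann$strand[i] != ann$strand[i + 1]) ov <- TRUE
  expect_true(ov)

  ann0 <- build_annotation(g, 6, n_genes = 10, operon_fraction = 0)
  expect_true(all(is.na(ann0$operon_id)))
  expect_error(build_annotation(build_genome(1, length = 5000), 1,
                                n_genes = 40),
               "infeasible")
})

test_that("iCLIP simulation is deterministic and conserves molecules", {
  w <- world
  s1 <- simulate_iclip_library(w$genome, w$annotation, w$manifest,
                               "Rrp4_1", 200, seed = 9)
  s2 <- simulate_iclip_library(w$genome, w$annotation, w$manifest,
                               "Rrp4_1", 200, seed = 9)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 200)
  expect_equal(nrow(s1$reads), sum(s1$truth$n_copies))
  expect_error(simulate_iclip_library(w$genome, w$annotation, w$manifest,
                                      "nope", 10),
               "missing from barcode table")
})

test_that("no duplication means one distinct read per molecule", {
  w <- world
  man <- ground_truth_manifest(w$genome, w$annotation, seed = 3,
                               duplication_rate = 0, n_circles = 0,
                               tail_fraction = 0)
  s <- simulate_iclip_library(w$genome, w$annotation, man, "Rrp4_1", 100,
                              seed = 4)
  expect_equal(nrow(s$reads), 100)
  expect_equal(uniqueN(s$reads$seq), 100)
})

test_that("truncation convention: insert starts one nt 3' of the crosslink", {
  w <- world
  s <- simulate_iclip_library(w$genome, w$annotation, w$manifest,
                              "Rrp41_1", 150, seed = 12)
  lin <- s$truth[class == "linear"]
  for (i in seq_len(nrow(lin))) {
    r <- lin[i]
    first <- substr(r$insert, 1, 1)
    expected <- if (r$strand == "+")
      substr(w$genome[[r$replicon]], r$crosslink + 2, r$crosslink + 2)
    else revcomp(substr(w$genome[[r$replicon]], r$crosslink, r$crosslink))
    expect_identical(first, expected)
  }
})

test_that("junction reads match the circularized sequence by construction", {
  w <- world
  s <- simulate_iclip_library(w$genome, w$annotation, w$manifest,
                              "Rrp4_2", 120, seed = 13)
  jn <- s$truth[class == "junction"]
  expect_gt(nrow(jn), 0)
  for (i in seq_len(nrow(jn))) {
    r <- jn[i]
    cc <- w$manifest$circles[circle_id == r$circle_id]
    circ2 <- strrep(seq_extract(w$genome, cc$replicon, cc$circ_start,
                                cc$circ_end, cc$strand), 2)
    expect_true(grepl(r$insert, circ2, fixed = TRUE))
    # and the insert is NOT a contiguous genomic (linear) sequence
    expect_equal(length(oracle_occurrences(r$insert,
                                           w$genome[[r$replicon]])), 0L)
  }
})

test_that("planted tails are non-extendable and A-rich by design", {
  w <- world
  man <- ground_truth_manifest(w$genome, w$annotation, seed = 3,
                               tail_fraction = 1, n_circles = 0)
  s <- simulate_iclip_library(w$genome, w$annotation, man, "Trx_1", 400,
                              seed = 14)
  tl <- s$truth[class == "tail"]
  expect_equal(nrow(tl), 400)
  # anchor part = insert minus tail matches the genome; next templated base
  # differs from the first tail base
  for (i in seq_len(min(nrow(tl), 50))) {
    r <- tl[i]
    anchor <- substr(r$insert, 1, nchar(r$insert) - nchar(r$tail))
    occ <- oracle_occurrences(
      if (r$strand == "+") anchor else revcomp(anchor),
      w$genome[[r$replicon]])
    expect_gt(length(occ), 0)
  }
  frac_a <- mean(strsplit(paste0(tl$tail, collapse = ""), "")[[1]] == "A")
  expect_lt(abs(frac_a - 0.73), 0.05)
})

test_that("rnaseq simulation respects abundances and determinism", {
  g <- build_genome(21, length = 20000)
  ann <- data.table(gene_id = c("a", "b"), replicon = "chr1",
                    start = c(1000L, 5000L), end = c(3000L, 7000L),
                    strand = c("+", "-"), biotype = "protein_coding",
                    operon_id = NA_character_)
  man <- ground_truth_manifest(g, ann, seed = 1, n_circles = 0)
  s <- simulate_rnaseq_library(g, ann, man, 10000, seed = 2)
  counts <- table(s$truth$gene_id)
  # equal abundance, two genes: binomial 3 sd around 5000
  expect_lt(abs(counts[["a"]] - 5000), 3 * sqrt(10000 * 0.25))

  s2 <- simulate_rnaseq_library(g, ann, man, 10000, seed = 2)
  expect_identical(s$reads, s2$reads)

  s0 <- simulate_rnaseq_library(g, ann, man, 0, seed = 2)
  expect_equal(nrow(s0$reads), 0L)
})

test_that("write_simulation emits every declared file", {
  w <- world
  dir <- withr::local_tempdir()
  write_simulation(dir, w$genome, w$annotation, w$manifest,
                   n_molecules = 60, n_rnaseq = 100, seed = 5)
  files <- c("genome.fa", "annotation.gff3", "operons.tsv", "truth.tsv",
             "barcodes.tsv", "rnaseq.fq",
             paste0(names(w$manifest$barcode_table), ".fq"))
  for (f in files) expect_true(file.exists(file.path(dir, f)), label = f)
  tr <- fread(file.path(dir, "truth.tsv"))
  expect_equal(uniqueN(tr$molecule_id), nrow(tr))
})
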