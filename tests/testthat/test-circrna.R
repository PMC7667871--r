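# fixture: genome where a junction read's planted coordinates are already
# canonical (bases flanking the joint differ)
make_circ_genome <- function(seed = 81, length = 6000) {
  g <- build_genome(seed, length = length)
  s <- g[[1]]
  # force genome[999] != genome[1249] (0-based) so circle (1000,1250) is
  # canonical
  if (substr(s, 1000, 1000) == substr(s, 1250, 1250)) {
    substr(s, 1000, 1000) <- flip_base(substr(s, 1250, 1250))
    g[[1]] <- s
  }
  g
}

junction_read <- function(genome, cs, ce, a, b, strand = "+") {
  circ <- seq_extract(genome, names(genome)[1], cs, ce, strand)
  clen <- nchar(circ)
  paste0(substr(circ, clen - a + 1, clen), substr(circ, 1, b))
}

test_that("find_primary_fragment finds the longest match and its flank", {
  g <- make_circ_genome()
  set.seed(82)
  rand20 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  read <- paste0(seq_extract(g, "chr1", 200, 230), rand20)
  hit <- find_primary_fragment(read, g)
  expect_equal(hit$qstart, 0L)
  expect_gte(hit$qend, 30L)      # may extend by chance into the random part
  expect_equal(hit$sstart, 200L)
  expect_equal(hit$strand, "+")
  # oracle: reported length equals the longest common substring
  expect_equal(hit$qend - hit$qstart, oracle_lcs_len(read, g))

  # below the 20-nt minimum -> none
  short <- paste0(substr(seq_extract(g, "chr1", 300, 319), 1, 19),
                  strrep("A", 31))
  hit2 <- find_primary_fragment(short, g)
  if (!is.null(hit2)) expect_gte(hit2$qend - hit2$qstart, 20L)

  # fully matching read has no unaligned flank -> none
  expect_null(find_primary_fragment(seq_extract(g, "chr1", 400, 450), g))
})

test_that("find_secondary_fragment honors span and single-position rules", {
  g <- make_circ_genome()
  anchor <- list(qstart = 0L, qend = 30L, replicon = "chr1",
                 sstart = 1220L, send = 1250L, strand = "+")
  flank <- seq_extract(g, "chr1", 1000, 1020)
  sec <- find_secondary_fragment(flank, g, anchor)
  expect_equal(sec$sstart, 1000L)

  # same flank planted at two in-range loci -> none
  g2 <- g
  s <- g2[[1]]
  substr(s, 2001, 2020) <- flank
  g2[[1]] <- s
  expect_null(find_secondary_fragment(flank, g2, anchor))

  # out of span -> none
  far_anchor <- list(qstart = 0L, qend = 30L, replicon = "chr1",
                     sstart = 5500L, send = 5530L, strand = "+")
  expect_null(find_secondary_fragment(flank, g, far_anchor,
                                      max_span = 4000L))
})

test_that("call_junction demands permuted order and canonicalizes", {
  g <- make_circ_genome()
  f5 <- list(qstart = 0L, qend = 30L, replicon = "chr1", sstart = 1220L,
             send = 1250L, strand = "+")
  f3 <- list(qstart = 30L, qend = 50L, replicon = "chr1", sstart = 1000L,
             send = 1020L, strand = "+")
  jc <- call_junction(f5, f3, g)
  expect_equal(jc$circ_start, 1000L)
  expect_equal(jc$circ_end, 1250L)

  # colinear fragments -> none
  c5 <- list(qstart = 0L, qend = 30L, replicon = "chr1", sstart = 100L,
             send = 130L, strand = "+")
  c3 <- list(qstart = 30L, qend = 45L, replicon = "chr1", sstart = 135L,
             send = 150L, strand = "+")
  expect_null(call_junction(c5, c3, g))
})

test_that("detect_junctions recovers a planted junction read", {
  g <- make_circ_genome()
  read <- junction_read(g, 1000L, 1250L, 30L, 20L)
  jc <- detect_junctions(read_table(read), g)
  expect_equal(nrow(jc), 1L)
  expect_equal(jc$circ_start, 1000L)
  expect_equal(jc$circ_end, 1250L)
  expect_equal(jc$strand, "+")
})

test_that("junction calls are sound and agree with brute force (5 kb)", {
  g <- build_genome(83, length = 5000)
  set.seed(84)
  reads <- character(0)
  # planted junctions, both strands, various splits
  for (k in 1:8) {
    cs <- sample(200:2000, 1)
    clen <- sample(150:900, 1)
    st <- sample(c("+", "-"), 1)
    a <- sample(20:30, 1)
    b <- sample(15:25, 1)
    reads <- c(reads, junction_read(g, cs, cs + clen, a, b, st))
  }
  # linear and random reads must not call
  for (k in 1:6) {
    s0 <- sample(100:4900, 1)
    reads <- c(reads, seq_extract(g, "chr1", s0, s0 + 50))
  }
  reads <- c(reads, replicate(4, paste(
    sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")))
  calls <- detect_junctions(read_table(reads), g)
  # soundness: every call is in the oracle's enumeration for its read
  for (i in seq_len(nrow(calls))) {
    rid <- calls$read_id[i]
    seq <- reads[match(rid, sprintf("r%03d", seq_along(reads)))]
    oset <- oracle_junctions(seq, g)
    expect_true(nrow(merge(calls[i, .(replicon, strand, circ_start,
                                      circ_end)],
                           oset)) == 1,
                label = paste("call for", rid, "in oracle set"))
  }
  # completeness on the planted, uniquely explainable junction reads
  for (i in 1:8) {
    oset <- oracle_junctions(reads[i], g)
    if (nrow(oset) == 1) {
      got <- calls[read_id == sprintf("r%03d", i)]
      expect_equal(nrow(got), 1L, label = paste("planted read", i))
      expect_equal(got$circ_start, oset$circ_start)
      expect_equal(got$circ_end, oset$circ_end)
    }
  }
  # linear/random reads: no calls
  expect_false(any(calls$read_id %in% sprintf("r%03d", 9:18)))
})

test_that("junction soundness: read equals circularized sequence slice", {
  w <- world
  s <- simulate_iclip_library(w$genome, w$annotation, w$manifest,
                              "Rrp4_1", 150, seed = 85)
  pre <- preprocess_reads(s$reads, w$manifest$barcode_table)
  mp <- map_reads(w$genome, pre$libraries$Rrp4_1)
  jc <- detect_junctions(mp$unmapped, w$genome)
  expect_gt(nrow(jc), 0)
  seqs <- pre$libraries$Rrp4_1[match(jc$read_id, id), seq]
  for (i in seq_len(nrow(jc))) {
    circ <- seq_extract(w$genome, jc$replicon[i], jc$circ_start[i],
                        jc$circ_end[i], jc$strand[i])
    expect_true(grepl(seqs[i], strrep(circ, 2), fixed = TRUE),
                label = paste("junction read", i))
  }
})

test_that("aggregate_candidates applies the 10-reads/3-libraries rule", {
  mk <- function(n) data.table(
    read_id = sprintf("x%d", seq_len(n)), replicon = "chr1", strand = "+",
    circ_start = 1000L, circ_end = 1250L)
  calls <- list(L1 = mk(12), L2 = mk(11), L3 = mk(10), Ctrl = mk(50))
  out <- aggregate_candidates(calls, eligible_libraries = c("L1", "L2",
                                                            "L3"))
  expect_true(out$kept)
  expect_equal(out$Ctrl, 50L)  # reported, not qualifying

  calls2 <- list(L1 = mk(12), L2 = mk(11), L3 = mk(9))
  out2 <- aggregate_candidates(calls2)
  expect_false(out2$kept)

  calls3 <- list(L1 = mk(10), L2 = mk(10), L3 = mk(10), L4 = mk(0))
  out3 <- aggregate_candidates(calls3)
  expect_true(out3$kept)
})
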