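# Synthetic iCLIP / RNA-Seq world with planted ground truth.
#
# The generator emulates the sequencing library structure the pipeline was
# designed for: 75-nt single reads carrying a 9-nt composite 5' barcode
# (3 random + 4 experimental + 1... see barcode_scheme: 3 random + 4
# experimental + 2 random), truncation-type cDNA inserts starting one nt 3'
# of the crosslinked base (transcript orientation), junction-spanning reads
# from planted circular RNAs, reads ending in non-templated A-rich tails,
# a 3' sequencing adapter, and Poisson PCR duplication.

ICLIP_ADAPTER <- "TGAGATCGGA"
# bases a sequencer reads past the adapter (RT primer region); content is
# irrelevant downstream because the adapter clipper removes everything 3'
READTHROUGH_PAD <- "AGATCGGAAGAGCGTCGTGGATCCTGAACCGC"

#' Default library -> experimental 4-mer barcode table
#'
#' Six libraries: two replicates each for the two exosome cap/core subunits
#' (Rrp4, Rrp41) and a Trx control.
#' @export
default_barcode_table <- function() {
  c(Rrp4_1 = "GGTT", Rrp4_2 = "TGGC", Rrp41_1 = "GGTC",
    Rrp41_2 = "CGGA", Trx_1 = "GGCA", Trx_2 = "CCGG")
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# uniform draw from lo..hi, safe when lo == hi (avoids sample()'s scalar
# expansion)
runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_dna <- function(n, len, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (n == 0) return(character())
  m <- matrix(sample(names(probs), n * len, replace = TRUE, prob = probs),
              nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Build a random genome
#'
#' @param seed Integer seed (NULL: use current RNG state).
#' @param n_replicons Number of replicons.
#' @param length Length of each replicon (>= 5000).
#' @param gc Target GC fraction.
#' @return Named character vector of DNA strings.
#' @export
build_genome <- function(seed = 1L, n_replicons = 1L, length = 50000L,
                         gc = 0.5) {
  if (length < 5000) stop("replicon length must be >= 5000")
  with_seed_maybe(seed, {
    g <- random_dna(n_replicons, length, gc)
    setNames(g, paste0("chr", seq_len(n_replicons)))
  })
}

round_mix <- function(mix, n) {
  # deterministic largest-remainder apportionment of n genes over biotypes
  raw <- mix / sum(mix) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  base
}

#' Build a random gene annotation on a genome
#'
#' Genes are packed left to right with intergenic gaps; one designed
#' convergent pair overlaps by 30 nt at the 3' ends (substrate for
#' antisense/3'-UTR analyses). All gene lengths are multiples of 10 and
#' >= 100 so deciles are >= 10 nt.
#'
#' @param genome Named character vector.
#' @param seed Integer seed.
#' @param n_genes Number of genes (>= 4).
#' @param biotype_mix Named numeric mix over biotypes.
#' @param operon_fraction Approximate fraction of genes placed in operons.
#' @return data.table: gene_id, replicon, start, end, strand, biotype,
#'   operon_id.
#' @export
build_annotation <- function(genome, seed = 1L, n_genes = 40L,
                             biotype_mix = c(protein_coding = 0.8,
                                             tRNA = 0.1, rRNA = 0.05,
                                             other = 0.05),
                             operon_fraction = 0.3) {
  check_genome(genome)
  stopifnot(n_genes >= 4)
  with_seed_maybe(seed, {
    counts <- round_mix(biotype_mix, n_genes)
    biotypes <- rep(names(counts), counts)
    # the convergent pair must be protein_coding; force two such slots
    if (counts["protein_coding"] < 2)
      stop("need at least two protein_coding genes for the convergent pair")
    biotypes <- sample(biotypes)
    # move two protein_coding genes to the designated pair slots
    pc_idx <- which(biotypes == "protein_coding")
    pair_slot <- pc_idx[1]

    len_for <- function(bt) {
      switch(bt,
        protein_coding = sample(seq(300L, 1200L, 10L), 1),
        rRNA = sample(seq(1500L, 2500L, 10L), 1),
        tRNA = sample(seq(100L, 160L, 10L), 1),
        other = sample(seq(200L, 600L, 10L), 1))
    }

    margin <- 300L
    rep_name <- names(genome)[1]
    L <- nchar(genome[[rep_name]])
    pos <- margin
    rows <- vector("list", n_genes)
    i <- 1L
    gi <- 1L
    while (gi <= n_genes) {
      bt <- biotypes[gi]
      len <- len_for(bt)
      gap <- sample(60:150, 1)
      if (gi == pair_slot && gi < n_genes &&
          biotypes[gi + 1L] == "protein_coding") {
        len2 <- len_for("protein_coding")
        ov <- 30L
        if (pos + len + len2 - ov > L - margin)
          stop("infeasible packing: genome too small for requested genes")
        rows[[gi]] <- list(pos, pos + len, "+", bt)
        rows[[gi + 1L]] <- list(pos + len - ov, pos + len - ov + len2,
                                "-", "protein_coding")
        pos <- pos + len - ov + len2 + gap
        gi <- gi + 2L
        next
      }
      if (pos + len > L - margin)
        stop("infeasible packing: genome too small for requested genes")
      rows[[gi]] <- list(pos, pos + len, sample(c("+", "-"), 1), bt)
      pos <- pos + len + gap
      gi <- gi + 1L
    }
    ann <- rbindlist(lapply(rows, function(r)
      data.table(start = r[[1]], end = r[[2]], strand = r[[3]],
                 biotype = r[[4]])))
    ann[, `:=`(gene_id = sprintf("g%03d", .I), replicon = rep_name,
               operon_id = NA_character_)]

    if (operon_fraction > 0) {
      target <- round(operon_fraction * n_genes)
      assigned <- 0L
      op <- 1L
      gi <- 1L
      while (assigned < target && gi < n_genes) {
        run_len <- min(sample(2:3, 1), n_genes - gi + 1L)
        idx <- gi:(gi + run_len - 1L)
        if (length(unique(ann$strand[idx])) == 1 &&
            all(is.na(ann$operon_id[idx]))) {
          ann$operon_id[idx] <- sprintf("op%02d", op)
          op <- op + 1L
          assigned <- assigned + run_len
          gi <- gi + run_len
        } else gi <- gi + 1L
      }
    }
    setcolorder(ann, c("gene_id", "replicon", "start", "end", "strand",
                       "biotype", "operon_id"))
    ann[]
  })
}

canonicalize_circle <- function(genome, replicon, cs, ce) {
  # left-shift the junction across identical flanking bases so equivalent
  # (start, end) pairs collapse to one representative
  s <- genome[[replicon]]
  while (cs > 0 && substr(s, cs, cs) == substr(s, ce, ce)) {
    cs <- cs - 1L
    ce <- ce - 1L
  }
  c(cs, ce)
}

#' Assemble the ground-truth manifest for a simulation
#'
#' The manifest is the generator's contract with the tests: planted circles,
#' the tail base/length model, crosslink placement weights, the PCR
#' duplication rate, the barcode table and per-gene RNA-Seq abundances.
#'
#' @param genome,annotation Synthetic genome and gene table.
#' @param seed Integer seed used to choose circle coordinates.
#' @param n_circles Number of planted circular RNAs.
#' @param junction_reads_eligible,junction_reads_control Junction molecules
#'   planted per circle in each eligible (CoIP) / control library.
#' @param tail_fraction Fraction of iCLIP molecules carrying a 3' tail.
#' @param tail_a Per-position adenosine probability of the tail model.
#' @param tail_mean_len Mean of the (geometric, >= 1) tail length law.
#' @param tail_max_len Maximal analyzed/planted tail length.
#' @param decile_weights Length-10 weights for crosslink placement along
#'   gene bodies (uniform by default).
#' @param hotspot_offset,hotspot_fraction Optional planted crosslink hotspot
#'   at a fixed offset from gene starts (transcript orientation; negative =
#'   upstream) and the fraction of linear molecules assigned to it.
#' @param duplication_rate Expected PCR copies per molecule (>= 1 scale;
#'   copies = 1 + Poisson(max(0, rate - 1))).
#' @param barcode_table Named character vector library -> 4-mer.
#' @param control_libraries Libraries treated as controls (not eligible for
#'   circRNA candidate support).
#' @param rnaseq_abundance Named per-gene weights for RNA-Seq read sampling
#'   (default: equal).
#' @export
ground_truth_manifest <- function(genome, annotation, seed = 1L,
                                  n_circles = 3L,
                                  junction_reads_eligible = 15L,
                                  junction_reads_control = 2L,
                                  tail_fraction = 0.15,
                                  tail_a = 0.73,
                                  tail_mean_len = 4,
                                  tail_max_len = 40L,
                                  decile_weights = rep(1, 10),
                                  hotspot_offset = NULL,
                                  hotspot_fraction = 0,
                                  duplication_rate = 2,
                                  barcode_table = default_barcode_table(),
                                  control_libraries = grep(
                                    "^Trx", names(barcode_table),
                                    value = TRUE),
                                  rnaseq_abundance = NULL) {
  check_genome(genome)
  if (any(nchar(barcode_table) != 4) || anyDuplicated(barcode_table))
    stop("experimental barcodes must be unique 4-mers")
  stopifnot(length(decile_weights) == 10, all(decile_weights >= 0),
            tail_a >= 0, tail_a <= 1, tail_fraction >= 0, tail_fraction <= 1)
  other <- (1 - tail_a) / 3
  tail_base_probs <- matrix(rep(c(A = tail_a, C = other, G = other,
                                  T = other), tail_max_len),
                            nrow = 4, dimnames = list(c("A", "C", "G", "T")))
  circles <- with_seed_maybe(seed, {
    hosts <- annotation[order(factor(biotype,
                                     levels = c("rRNA", "protein_coding",
                                                "other", "tRNA")),
                              -(end - start))]
    hosts <- head(hosts, n_circles)
    if (nrow(hosts) < n_circles) stop("not enough genes to host circles")
    rbindlist(lapply(seq_len(nrow(hosts)), function(i) {
      h <- hosts[i]
      off <- sample(0:20, 1)
      clen <- min(sample(150:400, 1), h$end - h$start - off)
      cs <- h$start + off
      ce <- cs + clen
      cc <- canonicalize_circle(genome, h$replicon, cs, ce)
      data.table(circle_id = sprintf("circ%02d", i), replicon = h$replicon,
                 circ_start = cc[1], circ_end = cc[2], strand = h$strand)
    }))
  })
  eligible <- setdiff(names(barcode_table), control_libraries)
  jr <- lapply(names(barcode_table), function(lib)
    if (lib %in% eligible) junction_reads_eligible else junction_reads_control)
  names(jr) <- names(barcode_table)
  if (is.null(rnaseq_abundance))
    rnaseq_abundance <- setNames(rep(1, nrow(annotation)),
                                 annotation$gene_id)
  structure(list(
    circles = circles,
    junction_reads = jr,
    tail_fraction = tail_fraction,
    tail_base_probs = tail_base_probs,
    tail_mean_len = tail_mean_len,
    tail_max_len = as.integer(tail_max_len),
    decile_weights = decile_weights / sum(decile_weights),
    hotspot_offset = hotspot_offset,
    hotspot_fraction = hotspot_fraction,
    duplication_rate = duplication_rate,
    barcode_table = barcode_table,
    control_libraries = control_libraries,
    eligible_libraries = eligible,
    rnaseq_abundance = rnaseq_abundance,
    seed = seed
  ), class = "exo_manifest")
}

# sample one crosslink position (0-based) for a gene row, in transcript
# orientation; returns genomic position of the crosslinked base
sample_crosslink <- function(gene, weights) {
  L <- gene$end - gene$start
  d <- sample.int(10, 1, prob = weights)
  lo <- floor((d - 1) * L / 10)
  hi <- floor(d * L / 10) - 1
  local <- runif_int(lo, hi)
  if (gene$strand == "+") gene$start + local else gene$end - 1L - local
}

# genomic insert of length len starting one nt 3' of crosslink x
# (transcript orientation); returns NULL when it would leave the replicon
insert_from_crosslink <- function(genome, replicon, x, strand, len) {
  L <- nchar(genome[[replicon]])
  if (strand == "+") {
    if (x + 1 + len > L) len <- L - x - 1
    if (len < 16) return(NULL)
    seq_extract(genome, replicon, x + 1, x + 1 + len, "+")
  } else {
    if (x - len < 0) len <- x
    if (len < 16) return(NULL)
    seq_extract(genome, replicon, x - len, x, "-")
  }
}

sample_tail <- function(manifest) {
  t_len <- min(1L + rgeom(1, prob = 1 / manifest$tail_mean_len),
               manifest$tail_max_len)
  bases <- vapply(seq_len(t_len), function(k)
    sample(rownames(manifest$tail_base_probs), 1,
           prob = manifest$tail_base_probs[, k]), character(1))
  paste0(bases, collapse = "")
}

# next templated read base 3'-ward of an anchor ending at transcript
# position (genomic x_end exclusive on +, x_start on -)
next_template_base <- function(genome, replicon, strand, boundary) {
  L <- nchar(genome[[replicon]])
  if (strand == "+") {
    if (boundary >= L) return(NA_character_)
    substr(genome[[replicon]], boundary + 1L, boundary + 1L)
  } else {
    if (boundary <= 0) return(NA_character_)
    revcomp(substr(genome[[replicon]], boundary, boundary))
  }
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(b)) < rate
    if (any(hit))
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste0(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate one iCLIP library with planted ground truth
#'
#' Each molecule is a truncation product: its insert starts one nucleotide
#' 3' of the crosslinked base in transcript orientation. Junction molecules
#' read across a planted circle's end -> start joint; tail molecules end in
#' a non-templated suffix drawn from the manifest's tail model. Reads carry
#' a 9-nt composite barcode (3 random + 4 experimental + 2 random), the 3'
#' adapter when the insert is short, and Poisson PCR duplication.
#'
#' @param genome,annotation,manifest The synthetic world.
#' @param library Library label (must be in the manifest's barcode table).
#' @param n_molecules Total distinct molecules (includes planted junction
#'   and tail molecules).
#' @param seed Integer seed.
#' @param read_length Sequenced read length (default 75).
#' @param insert_range Uniform range of linear insert lengths.
#' @param error_rate Per-base substitution rate (default 0).
#' @return List of class `sim_library`: `reads` (FASTQ table) and `truth`
#'   (one row per molecule).
#' @export
simulate_iclip_library <- function(genome, annotation, manifest, library,
                                   n_molecules, seed = 1L,
                                   read_length = 75L,
                                   insert_range = c(30L, 60L),
                                   error_rate = 0) {
  if (!library %in% names(manifest$barcode_table))
    stop("library '", library, "' missing from barcode table")
  with_seed_maybe(seed, {
    bc4 <- manifest$barcode_table[[library]]
    circles <- manifest$circles
    n_junc_per_circle <- manifest$junction_reads[[library]]
    n_junction <- nrow(circles) * n_junc_per_circle
    n_tail <- round(manifest$tail_fraction * n_molecules)
    n_linear <- n_molecules - n_junction - n_tail
    if (n_linear < 0)
      stop("n_molecules too small for planted junction/tail molecules")

    classes <- c(rep("junction", n_junction), rep("tail", n_tail),
                 rep("linear", n_linear))
    circle_of <- c(rep(circles$circle_id, each = n_junc_per_circle),
                   rep(NA_character_, n_tail + n_linear))
    genes <- annotation

    rows <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      cls <- classes[i]
      if (cls == "junction") {
        cc <- circles[circle_id == circle_of[i]]
        clen <- cc$circ_end - cc$circ_start
        total <- runif_int(50L, 60L)
        total <- min(total, clen)  # never wrap more than once
        a <- runif_int(25L, total - 25L)
        b <- total - a
        circ_seq <- seq_extract(genome, cc$replicon, cc$circ_start,
                                cc$circ_end, cc$strand)
        insert <- paste0(substr(circ_seq, clen - a + 1, clen),
                         substr(circ_seq, 1, b))
        rows[[i]] <- list(class = cls, replicon = cc$replicon,
                          strand = cc$strand, crosslink = NA_integer_,
                          gene_id = NA_character_, circle_id = cc$circle_id,
                          insert = insert, tail = NA_character_)
      } else if (cls == "tail") {
        tail_seq <- sample_tail(manifest)
        ok <- FALSE
        for (try in 1:100) {
          g <- genes[sample.int(nrow(genes), 1)]
          x <- sample_crosslink(g, manifest$decile_weights)
          a <- runif_int(25L, 45L)
          anchor <- insert_from_crosslink(genome, g$replicon, x, g$strand, a)
          if (is.null(anchor)) next
          a <- nchar(anchor)
          boundary <- if (g$strand == "+") x + 1L + a else x - a
          nb <- next_template_base(genome, g$replicon, g$strand, boundary)
          if (!is.na(nb) && nb != substr(tail_seq, 1, 1)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place a non-extendable tail anchor")
        insert <- paste0(anchor, tail_seq)
        rows[[i]] <- list(class = cls, replicon = g$replicon,
                          strand = g$strand, crosslink = x,
                          gene_id = g$gene_id, circle_id = NA_character_,
                          insert = insert, tail = tail_seq)
      } else {
        repeat {
          g <- genes[sample.int(nrow(genes), 1)]
          if (!is.null(manifest$hotspot_offset) &&
              runif(1) < manifest$hotspot_fraction) {
            off <- manifest$hotspot_offset  # negative = upstream of start
            x <- if (g$strand == "+") g$start + off else g$end - 1L - off
            L <- nchar(genome[[g$replicon]])
            if (x < 0 || x >= L) next
          } else {
            x <- sample_crosslink(g, manifest$decile_weights)
          }
          len <- runif_int(insert_range[1], insert_range[2])
          insert <- insert_from_crosslink(genome, g$replicon, x,
                                          g$strand, len)
          if (!is.null(insert)) break
        }
        rows[[i]] <- list(class = cls, replicon = g$replicon,
                          strand = g$strand, crosslink = x,
                          gene_id = g$gene_id, circle_id = NA_character_,
                          insert = insert, tail = NA_character_)
      }
    }
    truth <- rbindlist(rows)
    truth[, molecule_id := sprintf("%s_m%05d", library, .I)]
    truth[, library := library]

    capacity <- read_length - 9L
    truth[, insert_seq := substr(insert, 1, capacity)]
    truth[class == "tail",
          tail_seq := substr(tail, 1,
                             pmax(0L, capacity - (nchar(insert) -
                                                  nchar(tail))))]
    truth[class != "tail", tail_seq := NA_character_]
    truth[, c("insert", "tail") := NULL]
    setnames(truth, c("insert_seq", "tail_seq"), c("insert", "tail"))

    barcodes <- paste0(random_dna(n_molecules, 3), bc4,
                       random_dna(n_molecules, 2))
    truth[, barcode := barcodes]
    full <- paste0(barcodes, truth$insert)
    short <- nchar(full) < read_length
    full[short] <- paste0(full[short], ICLIP_ADAPTER)
    pad <- strrep(READTHROUGH_PAD,
                  ceiling(read_length / nchar(READTHROUGH_PAD)))
    still <- nchar(full) < read_length
    full[still] <- paste0(full[still], pad)
    full <- substr(full, 1, read_length)
    full <- apply_errors(full, error_rate)
    truth[, read := full]
    truth[, n_copies := 1L + rpois(.N, max(0, manifest$duplication_rate - 1))]

    idx <- rep(seq_len(n_molecules), truth$n_copies)
    copy_no <- sequence(truth$n_copies)
    reads <- data.table(
      id = sprintf("%s_d%d", truth$molecule_id[idx], copy_no),
      seq = truth$read[idx],
      qual = strrep("I", nchar(truth$read[idx])),
      mult = 1L,
      library = library
    )
    setcolorder(truth, c("molecule_id", "library", "class", "replicon",
                         "strand", "crosslink", "gene_id", "circle_id",
                         "barcode", "insert", "tail", "read", "n_copies"))
    structure(list(reads = reads, truth = truth), class = "sim_library")
  })
}

#' Simulate an RNA-Seq library
#'
#' Reads are drawn uniformly within gene bodies, genes sampled
#' proportionally to the manifest's `rnaseq_abundance`; no barcodes or
#' adapters.
#'
#' @param genome,annotation,manifest The synthetic world.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param read_length Read length (shortened for genes below it).
#' @return `sim_library` with `reads` and a `truth` table (read -> gene).
#' @export
simulate_rnaseq_library <- function(genome, annotation, manifest,
                                    n_reads, seed = 1L, read_length = 50L) {
  with_seed_maybe(seed, {
    if (n_reads == 0) {
      return(structure(list(
        reads = data.table(id = character(), seq = character(),
                           qual = character(), mult = integer(),
                           library = character()),
        truth = data.table(read_id = character(), gene_id = character())),
        class = "sim_library"))
    }
    w <- manifest$rnaseq_abundance[annotation$gene_id]
    gi <- sample.int(nrow(annotation), n_reads, replace = TRUE, prob = w)
    g <- annotation[gi]
    len <- pmin(read_length, g$end - g$start)
    smax <- g$end - len
    starts <- g$start + floor(runif(n_reads) * (smax - g$start + 1))
    seqs <- vapply(seq_len(n_reads), function(i)
      seq_extract(genome, g$replicon[i], starts[i], starts[i] + len[i],
                  g$strand[i]), character(1))
    reads <- data.table(
      id = sprintf("rs_%06d", seq_len(n_reads)),
      seq = seqs,
      qual = strrep("I", len),
      mult = 1L,
      library = "RNASeq"
    )
    truth <- data.table(read_id = reads$id, gene_id = g$gene_id,
                        start = starts, end = starts + len,
                        strand = g$strand)
    structure(list(reads = reads, truth = truth), class = "sim_library")
  })
}

#' Simulate per-base coverage for one locus under two assays
#'
#' Independent Poisson coverage per position; used for enrichment-call
#' calibration experiments.
#'
#' @param length Locus length (nt).
#' @param iclip_rate,rnaseq_rate Mean per-base coverage of the two assays.
#' @param seed Integer seed.
#' @return List with numeric vectors `iclip` and `rnaseq`.
#' @export
simulate_locus_coverage <- function(length, iclip_rate = 30,
                                    rnaseq_rate = 10, seed = NULL) {
  with_seed_maybe(seed, list(iclip = rpois(length, iclip_rate),
                             rnaseq = rpois(length, rnaseq_rate)))
}

#' Write a complete simulated data set to disk
#'
#' Emits genome.fa, annotation.gff3, operons.tsv, one FASTQ per iCLIP
#' library, rnaseq.fq, truth.tsv and manifest fields as plain text.
#'
#' @param dir Output directory (created).
#' @param genome,annotation,manifest The synthetic world.
#' @param n_molecules iCLIP molecules per library.
#' @param n_rnaseq RNA-Seq reads.
#' @param seed Integer seed; per-library seeds are derived from it.
#' @return Invisible list of produced paths.
#' @export
write_simulation <- function(dir, genome, annotation, manifest,
                             n_molecules = 2000L, n_rnaseq = 20000L,
                             seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(genome, file.path(dir, "genome.fa"))
  write_gff3(annotation, file.path(dir, "annotation.gff3"))
  fwrite(annotation[!is.na(operon_id), .(gene_id, operon_id)],
         file.path(dir, "operons.tsv"), sep = "\t")
  libs <- names(manifest$barcode_table)
  truth_all <- list()
  paths <- list()
  for (i in seq_along(libs)) {
    sl <- simulate_iclip_library(genome, annotation, manifest, libs[i],
                                 n_molecules, seed = seed + i)
    p <- file.path(dir, paste0(libs[i], ".fq"))
    write_fastq(sl$reads, p)
    truth_all[[i]] <- sl$truth
    paths[[libs[i]]] <- p
  }
  rs <- simulate_rnaseq_library(genome, annotation, manifest, n_rnaseq,
                                seed = seed + length(libs) + 1L)
  write_fastq(rs$reads, file.path(dir, "rnaseq.fq"))
  fwrite(rbindlist(truth_all), file.path(dir, "truth.tsv"), sep = "\t")
  fwrite(data.table(library = libs,
                    barcode4 = unname(manifest$barcode_table[libs])),
         file.path(dir, "barcodes.tsv"), sep = "\t")
  invisible(c(paths, list(rnaseq = file.path(dir, "rnaseq.fq"),
                          truth = file.path(dir, "truth.tsv"))))
}
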