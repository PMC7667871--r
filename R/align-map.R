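# Internal unique-best ungapped mapper. Replaces an external aligner at
# desk scale: exact-seed (16-mer hash) fast path for error-free reads, a
# mismatch-tolerant Biostrings fallback otherwise. Reads with >= 2
# locations tying at the best score are "ambiguous" and excluded
# downstream (the multimapper / MAPQ-filter equivalent).

SEED_LEN <- 16L

validate_read_seq <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("read sequence with non-ACGTN characters")
  invisible(seqs)
}

build_seed_index <- function(genome, k = SEED_LEN) {
  idx <- rbindlist(lapply(names(genome), function(rn) {
    s <- genome[[rn]]
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table(kmer = substring(s, starts, starts + k - 1L),
               replicon = rn, pos = starts - 1L)
  }))
  setkey(idx, kmer)
  idx
}

# verify candidate exact placements: does the full query match the genome
# at [pos, pos+len) on the plus strand?
verify_exact <- function(genome, cand, qlen) {
  if (nrow(cand) == 0) return(cand[0])
  L <- genome_lengths(genome)[cand$replicon]
  ok <- cand$pos + qlen <= L
  cand <- cand[ok]
  if (nrow(cand) == 0) return(cand)
  obs <- substring(genome[cand$replicon], cand$pos + 1L, cand$pos + qlen)
  cand[obs == cand$query]
}

#' Map many reads to a genome (unique-best, ungapped)
#'
#' @param genome Named character vector.
#' @param reads Read table (id, seq, mult, ...).
#' @param max_mismatches Maximal Hamming distance of the fallback search.
#' @param index Optional precomputed seed index (from repeated calls).
#' @return List: `alignments` (data.table id, replicon, start, end, strand,
#'   nm, mult), `unmapped` (read table), `ambiguous` (read table).
#' @export
map_reads <- function(genome, reads, max_mismatches = 2L, index = NULL) {
  check_genome(genome)
  validate_read_seq(reads$seq)
  if (is.null(index)) index <- build_seed_index(genome)
  res_aln <- list()
  status <- rep(NA_character_, nrow(reads))
  aln_rows <- vector("list", nrow(reads))

  too_short <- nchar(reads$seq) < SEED_LEN
  status[too_short] <- "unmapped"

  todo <- which(!too_short)
  if (length(todo)) {
    qseq <- reads$seq[todo]
    rcq <- revcomp(qseq)
    # exact path: all full-length exact matches are found via the first
    # k-mer of the (oriented) query
    cand_list <- list()
    for (ori in c("+", "-")) {
      qq <- if (ori == "+") qseq else rcq
      first <- substr(qq, 1, SEED_LEN)
      dt <- data.table(row = todo, query = qq, kmer = first,
                       qlen = nchar(qq), ori = ori)
      hits <- index[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      cand_list[[ori]] <- hits
    }
    cand <- rbindlist(cand_list)
    if (nrow(cand)) {
      L <- genome_lengths(genome)[cand$replicon]
      cand <- cand[pos + qlen <= L]
    }
    if (nrow(cand)) {
      obs <- substring(genome[cand$replicon], cand$pos + 1L,
                       cand$pos + cand$qlen)
      cand <- cand[obs == query]
    }
    exact_n <- if (nrow(cand)) cand[, .N, by = row] else
      data.table(row = integer(), N = integer())
    uniq_rows <- exact_n[N == 1L, row]
    multi_rows <- exact_n[N >= 2L, row]
    status[multi_rows] <- "ambiguous"
    if (length(uniq_rows)) {
      hit <- cand[row %in% uniq_rows]
      aln_exact <- data.table(
        id = reads$id[hit$row], replicon = hit$replicon,
        start = hit$pos, end = hit$pos + hit$qlen,
        strand = hit$ori, nm = 0L, mult = reads$mult[hit$row])
      res_aln[["exact"]] <- aln_exact
      status[uniq_rows] <- "mapped"
    }
    # fallback: no exact match anywhere -> mismatch-tolerant scan
    fb <- todo[is.na(status[todo])]
    if (length(fb) && max_mismatches > 0) {
      subjects <- lapply(genome, Biostrings::DNAString)
      for (i in fb) {
        best <- approx_best_hits(subjects, genome, reads$seq[i],
                                 max_mismatches)
        if (is.null(best)) { status[i] <- "unmapped"; next }
        if (nrow(best) >= 2) { status[i] <- "ambiguous"; next }
        status[i] <- "mapped"
        aln_rows[[i]] <- data.table(
          id = reads$id[i], replicon = best$replicon, start = best$start,
          end = best$end, strand = best$strand, nm = best$nm,
          mult = reads$mult[i])
      }
    }
    status[todo][is.na(status[todo])] <- "unmapped"
  }
  status[is.na(status)] <- "unmapped"

  alignments <- rbindlist(c(res_aln, aln_rows[!vapply(aln_rows, is.null,
                                                      logical(1))]))
  if (nrow(alignments) == 0)
    alignments <- data.table(id = character(), replicon = character(),
                             start = integer(), end = integer(),
                             strand = character(), nm = integer(),
                             mult = integer())
  list(alignments = alignments,
       unmapped = reads[status == "unmapped"],
       ambiguous = reads[status == "ambiguous"])
}

# all minimum-mismatch ungapped placements of seq (both strands), up to
# max_mismatches; NULL when none
approx_best_hits <- function(subjects, genome, seq, max_mismatches) {
  pats <- list(`+` = Biostrings::DNAString(seq),
               `-` = Biostrings::DNAString(revcomp(seq)))
  hits <- list()
  for (rn in names(subjects)) {
    for (ori in c("+", "-")) {
      m <- Biostrings::matchPattern(pats[[ori]], subjects[[rn]],
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      st <- Biostrings::start(m)
      nm <- vapply(seq_along(m), function(j)
        Biostrings::neditAt(pats[[ori]], subjects[[rn]], at = st[j],
                            with.indels = FALSE), integer(1))
      hits[[length(hits) + 1L]] <- data.table(
        replicon = rn, start = st - 1L, end = st - 1L + nchar(seq),
        strand = ori, nm = nm)
    }
  }
  if (!length(hits)) return(NULL)
  h <- rbindlist(hits)
  h <- h[nm <= max_mismatches]
  if (nrow(h) == 0) return(NULL)
  h[nm == min(nm)]
}

#' Map a single read
#'
#' @param genome Named character vector.
#' @param seq Read sequence.
#' @param max_mismatches Maximal Hamming distance.
#' @return List with `status` ("mapped" | "unmapped" | "ambiguous") and,
#'   when mapped, replicon, start, end, strand, nm.
#' @export
map_read <- function(genome, seq, max_mismatches = 2L) {
  r <- data.table(id = "q", seq = seq, qual = strrep("I", nchar(seq)),
                  mult = 1L, library = NA_character_)
  res <- map_reads(genome, r, max_mismatches)
  if (nrow(res$alignments) == 1) {
    a <- res$alignments
    list(status = "mapped", replicon = a$replicon, start = a$start,
         end = a$end, strand = a$strand, nm = a$nm)
  } else if (nrow(res$ambiguous) == 1) {
    list(status = "ambiguous")
  } else {
    list(status = "unmapped")
  }
}

#' Build stranded coverage tracks from unique alignments
#'
#' Every alignment increments each covered base; by default each collapsed
#' read counts once (`use_multiplicity = TRUE` weights by multiplicity).
#'
#' @param alignments Alignment table from [map_reads()].
#' @param genome Named character vector.
#' @param use_multiplicity Weight each alignment by its `mult` column.
#' @return A stranded coverage track (see [empty_track()]).
#' @export
build_coverage <- function(alignments, genome, use_multiplicity = FALSE) {
  track <- empty_track(genome)
  if (nrow(alignments) == 0) return(track)
  w <- if (use_multiplicity) alignments$mult else rep(1L, nrow(alignments))
  for (rn in unique(alignments$replicon)) {
    for (ori in c("+", "-")) {
      sel <- alignments$replicon == rn & alignments$strand == ori
      if (!any(sel)) next
      L <- nchar(genome[[rn]])
      # difference-array accumulation
      d <- numeric(L + 1L)
      st <- alignments$start[sel] + 1L
      en <- alignments$end[sel]
      ww <- w[sel]
      for (j in seq_along(st)) {
        d[st[j]] <- d[st[j]] + ww[j]
        d[en[j] + 1L] <- d[en[j] + 1L] - ww[j]
      }
      track[[rn]][[ori]] <- as.integer(cumsum(d[seq_len(L)]))
    }
  }
  track
}

#' Export alignments as BED6 (multiplicity in the score column)
#' @param alignments Alignment table.
#' @param path Output path.
#' @export
write_alignments_bed <- function(alignments, path) {
  lines <- paste(alignments$replicon, alignments$start, alignments$end,
                 alignments$id, alignments$mult, alignments$strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
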