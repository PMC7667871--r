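# Read-processing chain, in the fixed published order:
#   trim first base -> quality (5,95) -> quality (20,90) -> collapse
#   identical reads -> clip 3' adapter -> demultiplex / strip barcodes.
# Collapsing runs BEFORE adapter clipping on purpose: the random barcode is
# still part of the read string, so it separates biological duplicates.

#' Remove the first (poor-quality) base of every read
#'
#' Reads shorter than 2 nt are discarded and counted.
#'
#' @param reads Read table (id, seq, qual, mult, library).
#' @return Read table; attribute `n_discarded` carries the discard count.
#' @export
trim_first_base <- function(reads) {
  keep <- nchar(reads$seq) >= 2
  out <- reads[keep]
  out[, `:=`(seq = substr(seq, 2, nchar(seq)),
             qual = substr(qual, 2, nchar(qual)))]
  setattr(out, "n_discarded", sum(!keep))
  out[]
}

#' Filter reads on the percentage of high-quality bases
#'
#' A read is kept iff the percentage of bases with Phred quality >= `min_q`
#' is >= `min_pct` (boundaries inclusive, Phred+33).
#'
#' @param reads Read table.
#' @param min_q Minimum per-base quality.
#' @param min_pct Minimum percentage of bases reaching it.
#' @export
quality_filter <- function(reads, min_q, min_pct) {
  stopifnot(min_q >= 0, min_pct > 0, min_pct <= 100)
  if (nrow(reads) == 0) return(reads)
  pct <- vapply(reads$qual, function(q) {
    ph <- as.integer(charToRaw(q)) - 33L
    100 * sum(ph >= min_q) / length(ph)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- pct >= min_pct
  out <- reads[keep]
  setattr(out, "n_discarded", sum(!keep))
  out[]
}

#' Collapse byte-identical reads into one record with multiplicity
#'
#' Keyed on the full read string (barcodes still attached), so distinct
#' random barcodes keep biological duplicates apart. The representative
#' keeps the first read's id and qualities.
#'
#' @param reads Read table.
#' @export
collapse_identical <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  out <- reads[, .(id = id[1], qual = qual[1], mult = sum(mult),
                   library = library[1]), by = seq]
  setcolorder(out, c("id", "seq", "qual", "mult", "library"))
  out[]
}

clip_position <- function(seqs, adapter, min_overlap) {
  # first full occurrence, else a 3'-terminal prefix of the adapter of
  # length >= min_overlap; returns 0-based clip offset or NA
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  clip <- ifelse(pos > 0, pos - 1L, NA_integer_)
  n <- nchar(seqs)
  need <- is.na(clip)
  if (any(need)) {
    for (k in seq(nchar(adapter) - 1L, min_overlap)) {
      pre <- substr(adapter, 1, k)
      hit <- need & substr(seqs, n - k + 1L, n) == pre
      clip[hit] <- n[hit] - k
      need <- need & !hit
      if (!any(need)) break
    }
  }
  clip
}

#' Clip the 3' sequencing adapter
#'
#' The read is truncated at the first occurrence of the full adapter, or at
#' a 3'-terminal match of an adapter prefix of length >= `min_overlap`.
#' Reads left shorter than `min_len` are discarded.
#'
#' @param reads Read table.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimal terminal prefix length considered a match.
#' @param min_len Minimal read length kept after clipping.
#' @export
clip_adapter <- function(reads, adapter = ICLIP_ADAPTER, min_overlap = 5L,
                         min_len = 1L) {
  stopifnot(nchar(adapter) > 0)
  if (nrow(reads) == 0) return(reads)
  clip <- clip_position(reads$seq, adapter, min_overlap)
  out <- copy(reads)
  hit <- !is.na(clip)
  out[hit, `:=`(seq = substr(seq, 1, clip[hit]),
                qual = substr(qual, 1, clip[hit]))]
  keep <- nchar(out$seq) >= min_len
  res <- out[keep]
  setattr(res, "n_clipped", sum(hit))
  setattr(res, "n_discarded", sum(!keep))
  res[]
}

#' Demultiplex reads on the experimental barcode and strip barcodes
#'
#' Expects reads that have already lost their first base, so 8 barcode
#' nucleotides remain at the 5' end (2 random + 4 experimental + 2 random).
#' The first 2 nt are dropped, the next 4 must match a table entry exactly,
#' then 6 nt (experimental 4 + random 2) are removed. Unmatched reads land
#' in the "unassigned" bin; reads shorter than 9 nt are discarded.
#'
#' @param reads Read table.
#' @param barcode_table Named character vector library -> 4-mer.
#' @return Named list of read tables (one per library plus "unassigned");
#'   attribute `n_discarded` counts too-short reads.
#' @export
demultiplex <- function(reads, barcode_table) {
  if (any(nchar(barcode_table) != 4))
    stop("experimental barcodes must have length 4")
  if (anyDuplicated(barcode_table))
    stop("experimental barcodes must be unique")
  long <- nchar(reads$seq) >= 9
  n_short <- sum(!long)
  rr <- reads[long]
  bc <- substr(rr$seq, 3, 6)
  lib <- names(barcode_table)[match(bc, barcode_table)]
  lib[is.na(lib)] <- "unassigned"
  rr[, `:=`(seq = substr(seq, 9, nchar(seq)),
            qual = substr(qual, 9, nchar(qual)),
            library = lib)]
  out <- split(rr, by = "library")
  for (nm in setdiff(c(names(barcode_table), "unassigned"), names(out)))
    out[[nm]] <- rr[0]
  out <- out[c(names(barcode_table), "unassigned")]
  setattr(out, "n_discarded", n_short)
  out
}

#' Run the full preprocessing chain on one raw FASTQ table
#'
#' Order (fixed): trim first base, quality (5,95), quality (20,90),
#' collapse identical, clip adapter, demultiplex.
#'
#' @param reads Raw read table.
#' @param barcode_table Named character vector library -> 4-mer.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Adapter terminal-match minimum.
#' @param min_insert Minimal insert length kept after demultiplexing.
#' @return List: `libraries` (named list of read tables, inserts only),
#'   `stats` (data.table of per-stage counters).
#' @export
preprocess_reads <- function(reads, barcode_table,
                             adapter = ICLIP_ADAPTER,
                             min_overlap = 5L, min_insert = 16L) {
  n_input <- nrow(reads)
  r1 <- trim_first_base(reads)
  n_trim_drop <- attr(r1, "n_discarded")
  r2 <- quality_filter(r1, 5, 95)
  n_q1 <- attr(r2, "n_discarded")
  r3 <- quality_filter(r2, 20, 90)
  n_q2 <- attr(r3, "n_discarded")
  r4 <- collapse_identical(r3)
  n_collapsed <- nrow(r3) - nrow(r4)
  r5 <- clip_adapter(r4, adapter, min_overlap, min_len = 9L + 1L)
  n_clip <- attr(r5, "n_clipped")
  n_clip_drop <- attr(r5, "n_discarded")
  bins <- demultiplex(r5, barcode_table)
  n_demux_drop <- attr(bins, "n_discarded")
  # length filter on the final inserts
  short_dropped <- 0L
  for (nm in names(bins)) {
    keep <- nchar(bins[[nm]]$seq) >= min_insert
    short_dropped <- short_dropped + sum(!keep)
    bins[[nm]] <- bins[[nm]][keep]
  }
  stats <- data.table(
    stage = c("input", "trim_first_base_discarded", "quality_5_95_removed",
              "quality_20_90_removed", "collapsed_duplicates",
              "adapter_clipped", "adapter_discarded_short",
              "demux_discarded_short", "insert_discarded_short",
              "unassigned", "assigned"),
    count = c(n_input, n_trim_drop, n_q1, n_q2, n_collapsed, n_clip,
              n_clip_drop, n_demux_drop, short_dropped,
              nrow(bins[["unassigned"]]),
              sum(vapply(bins[setdiff(names(bins), "unassigned")],
                         nrow, integer(1))))
  )
  list(libraries = bins, stats = stats)
}
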