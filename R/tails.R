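# Non-templated 3' attachment (tail) detection: an unmapped, non-junction
# read whose 5' prefix maps perfectly and uniquely to the genome, extended
# maximally along the template; the remaining suffix is the tail. By the
# maximal-extension rule the reported tail is the minimal non-templated
# suffix, which systematically shortens tails after genomic A-runs (a
# documented bias).

# maximal templated extension of a located anchor; pos0 = 0-based genomic
# start of the occurrence of the (oriented) min_anchor prefix
extend_tail_anchor <- function(seq, genome, replicon, pos0, strand,
                               min_anchor) {
  n <- nchar(seq)
  L <- nchar(genome[[replicon]])
  k <- min_anchor
  if (strand == "+") {
    while (k < n && pos0 + k < L &&
           substr(seq, k + 1L, k + 1L) ==
           substr(genome[[replicon]], pos0 + k + 1L, pos0 + k + 1L))
      k <- k + 1L
    anchor <- c(start = pos0, end = pos0 + k)
  } else {
    # prefix matched rc(genome[pos0, pos0+min_anchor)); the read continues
    # toward lower genomic coordinates on the minus strand
    while (k < n && pos0 - (k - min_anchor) > 0 &&
           substr(seq, k + 1L, k + 1L) ==
           revcomp(substr(genome[[replicon]],
                          pos0 - (k - min_anchor),
                          pos0 - (k - min_anchor))))
      k <- k + 1L
    anchor <- c(start = pos0 + min_anchor - k, end = pos0 + min_anchor)
  }
  if (k >= n) return(NULL)  # fully templated: no tail
  list(replicon = replicon, start = unname(anchor["start"]),
       end = unname(anchor["end"]), strand = strand,
       tail = substr(seq, k + 1L, n))
}

#' Detect a non-templated 3' tail in one read
#'
#' The read's 5' prefix of length `min_anchor` must match the genome
#' perfectly at exactly one location (either strand); the match is then
#' extended 3'-ward as far as the read equals the template, and the
#' remaining suffix (>= 1 nt) is the tail.
#'
#' @param seq Read sequence.
#' @param genome Named character vector.
#' @param min_anchor Length of the 5' prefix used to locate the anchor.
#' @param max_mismatches Anchor-prefix mismatches tolerated (default 0 =
#'   perfect match; templated extension is always exact).
#' @return List(replicon, start, end, strand, tail) with the 0-based
#'   half-open anchor interval, or NULL (no unique anchor, no tail, or a
#'   read containing N).
#' @export
detect_tail <- function(seq, genome, min_anchor = 20L,
                        max_mismatches = 0L) {
  n <- nchar(seq)
  if (n <= min_anchor) return(NULL)
  if (grepl("N", seq, fixed = TRUE)) return(NULL)
  prefix <- substr(seq, 1, min_anchor)
  hits <- list()
  for (rn in names(genome)) {
    subj <- genome[[rn]]
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") prefix else revcomp(prefix)
      if (max_mismatches == 0) {
        m <- as.integer(gregexpr(pat, subj, fixed = TRUE)[[1]])
        if (m[1] == -1) next
      } else {
        mm <- Biostrings::matchPattern(pat, Biostrings::DNAString(subj),
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE)
        if (length(mm) == 0) next
        m <- Biostrings::start(mm)
      }
      for (p in m)
        hits[[length(hits) + 1L]] <- list(replicon = rn, pos = p - 1L,
                                          strand = ori)
    }
  }
  if (length(hits) != 1) return(NULL)  # no anchor or ambiguous anchor
  h <- hits[[1]]
  extend_tail_anchor(seq, genome, h$replicon, h$pos, h$strand, min_anchor)
}

#' Detect tails in a set of unmapped, non-junction reads
#'
#' Batch version of [detect_tail()] using a seed index to locate anchors.
#'
#' @param reads Read table.
#' @param genome Named character vector.
#' @param exclude_ids Read ids to skip (e.g. junction reads).
#' @param min_anchor Anchor prefix length (> seed length 16).
#' @param index Optional precomputed seed index (16-mers).
#' @return data.table: read_id, replicon, start, end, strand, tail.
#' @export
detect_tails <- function(reads, genome, exclude_ids = character(),
                         min_anchor = 20L, index = NULL) {
  stopifnot(min_anchor >= SEED_LEN)
  empty <- data.table(read_id = character(), replicon = character(),
                      start = integer(), end = integer(),
                      strand = character(), tail = character())
  if (nrow(reads) == 0) return(empty)
  rr <- reads[!id %in% exclude_ids]
  rr <- rr[nchar(seq) > min_anchor & !grepl("N", seq, fixed = TRUE)]
  if (nrow(rr) == 0) return(empty)
  if (is.null(index)) index <- build_seed_index(genome)
  # locate every genomic occurrence of each read's oriented anchor prefix
  cand <- rbindlist(lapply(c("+", "-"), function(ori) {
    pre <- substr(rr$seq, 1, min_anchor)
    if (ori == "-") pre <- revcomp(pre)
    dt <- data.table(row = seq_len(nrow(rr)), pre = pre,
                     kmer = substr(pre, 1, SEED_LEN), ori = ori)
    hits <- index[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0) return(NULL)
    L <- genome_lengths(genome)[hits$replicon]
    hits <- hits[pos + min_anchor <= L]
    if (nrow(hits) == 0) return(NULL)
    obs <- substring(genome[hits$replicon], hits$pos + 1L,
                     hits$pos + min_anchor)
    hits[obs == pre]
  }))
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  nloc <- cand[, .N, by = row]
  uniq <- nloc[N == 1L, row]
  cand <- cand[row %in% uniq]
  out <- list()
  for (i in seq_len(nrow(cand))) {
    h <- cand[i]
    t <- extend_tail_anchor(rr$seq[h$row], genome, h$replicon, h$pos,
                            h$ori, min_anchor)
    if (is.null(t)) next
    out[[length(out) + 1L]] <- data.table(
      read_id = rr$id[h$row], replicon = t$replicon, start = t$start,
      end = t$end, strand = t$strand, tail = t$tail)
  }
  if (!length(out)) return(empty)
  rbindlist(out)
}

#' Per-position and overall base composition of detected tails
#'
#' Position k aggregates base k of every tail of length >= k, up to
#' `max_len`; longer tails contribute only their first `max_len` bases to
#' the overall fractions.
#'
#' @param tails Character vector of tail sequences (or the table from
#'   [detect_tails()]).
#' @param max_len Maximal analyzed tail position.
#' @return List: `position` (data.table position, n, A/C/G/T counts and
#'   fractions), `overall` (named fractions), `length_hist` (table of tail
#'   lengths), `n_tails`.
#' @export
profile_tails <- function(tails, max_len = 40L) {
  if (is.data.frame(tails)) tails <- tails$tail
  if (length(tails) == 0) {
    return(list(position = data.table(position = integer(), n = integer(),
                                      A = integer(), C = integer(),
                                      G = integer(), T = integer()),
                overall = c(A = NaN, C = NaN, G = NaN, T = NaN),
                length_hist = table(integer()), n_tails = 0L))
  }
  lens <- nchar(tails)
  bases <- c("A", "C", "G", "T")
  pos_rows <- lapply(seq_len(min(max_len, max(lens))), function(k) {
    b <- substr(tails[lens >= k], k, k)
    cnt <- vapply(bases, function(x) sum(b == x), integer(1))
    data.table(position = k, n = length(b), t(cnt))
  })
  pos <- rbindlist(pos_rows)
  setnames(pos, c("position", "n", bases))
  for (b in bases) pos[, (paste0("f", b)) := get(b) / n]
  tot <- colSums(pos[, ..bases])
  overall <- tot / sum(tot)
  list(position = pos[], overall = overall,
       length_hist = table(lens), n_tails = length(tails))
}
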