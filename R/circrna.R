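# Circular-RNA junction detection in unmapped reads by a two-pass permuted
# split-fragment search: a primary exact fragment of >= 20 nt, then a
# secondary fragment of >= 12 nt in the unaligned flank, restricted to the
# primary's strand, within 4000 nt and at a single genomic location. A
# junction exists when the two fragments align in permuted genomic order.

#' Longest exact genomic match of a read ("primary fragment")
#'
#' Searches both strands for the longest substring of the read occurring in
#' the genome; ties break to the plus strand, then the lowest genome
#' coordinate, then the lowest read offset. Reads whose unaligned flank(s)
#' are all shorter than `min_flank` yield `NULL` (nothing left for a
#' secondary fragment).
#'
#' @param seq Read sequence (unmapped read).
#' @param genome Named character vector.
#' @param min_len Minimal primary fragment length.
#' @param min_flank Minimal unaligned flank worth keeping (secondary seed).
#' @param index Optional precomputed fragment index
#'   ([build_fragment_index()]).
#' @return List(qstart, qend, replicon, sstart, send, strand) with 0-based
#'   half-open read and genome intervals, or NULL.
#' @export
find_primary_fragment <- function(seq, genome, min_len = 20L,
                                  min_flank = 12L, index = NULL) {
  hit <- longest_match(seq, genome, min_len, strand = NULL, index = index)
  if (is.null(hit)) return(NULL)
  n <- nchar(seq)
  flank5 <- hit$qstart
  flank3 <- n - hit$qend
  if (flank5 < min_flank && flank3 < min_flank) return(NULL)
  hit
}

FRAG_SEED_LEN <- 12L

#' Build the k-mer index used by the fragment search
#' @param genome Named character vector.
#' @param k Seed length (must not exceed the smallest fragment searched).
#' @export
build_fragment_index <- function(genome, k = FRAG_SEED_LEN) {
  build_seed_index(genome, k)
}

# all maximal exact-match fragments (length >= k) between `seq` and the
# genome; strand NULL = both strands. Coordinates: read 0-based half-open
# in original read orientation, genome 0-based half-open plus strand.
maximal_fragments <- function(seq, genome, index, k = FRAG_SEED_LEN,
                              strand = NULL) {
  n <- nchar(seq)
  strands <- if (is.null(strand)) c("+", "-") else strand
  frags <- list()
  for (ori in strands) {
    q <- if (ori == "+") seq else revcomp(seq)
    if (n < k) next
    qpos <- 0:(n - k)
    dt <- data.table(kmer = substring(q, qpos + 1L, qpos + k), qpos = qpos)
    hits <- index[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0) next
    hits[, diag := pos - qpos]
    setorder(hits, replicon, diag, qpos)
    # seed runs on one diagonal belong to one maximal fragment; extend the
    # first seed of each run
    hits[, run_start := c(TRUE, diff(qpos) != 1L), by = .(replicon, diag)]
    seeds <- hits[run_start == TRUE]
    for (i in seq_len(nrow(seeds))) {
      rn <- seeds$replicon[i]
      s <- genome[[rn]]
      L <- nchar(s)
      q0 <- seeds$qpos[i]          # 0-based
      g0 <- seeds$pos[i]
      qe <- q0 + k                 # exclusive
      ge <- g0 + k
      while (q0 > 0 && g0 > 0 &&
             substr(q, q0, q0) == substr(s, g0, g0)) {
        q0 <- q0 - 1L; g0 <- g0 - 1L
      }
      while (qe < n && ge < L &&
             substr(q, qe + 1L, qe + 1L) == substr(s, ge + 1L, ge + 1L)) {
        qe <- qe + 1L; ge <- ge + 1L
      }
      frags[[length(frags) + 1L]] <- data.table(
        qstart = q0, qend = qe, replicon = rn, sstart = g0, send = ge,
        strand = ori)
    }
  }
  if (!length(frags))
    return(data.table(qstart = integer(), qend = integer(),
                      replicon = character(), sstart = integer(),
                      send = integer(), strand = character(),
                      len = integer()))
  ff <- unique(rbindlist(frags))
  # convert minus-strand read coordinates back to the original orientation
  if (nrow(ff[strand == "-"])) {
    ff[strand == "-", `:=`(qstart = n - qend, qend = n - qstart)]
  }
  ff[, len := qend - qstart]
  ff[]
}

# longest exact genomic match of `seq`; strand NULL = both strands.
# Best hit = longest, then "+" before "-", then lowest genome coordinate,
# then lowest read offset; n_locations counts genomic locations tying at
# the maximal length.
longest_match <- function(seq, genome, min_len, strand = NULL,
                          index = NULL) {
  if (nchar(seq) < min_len) return(NULL)
  k <- min(FRAG_SEED_LEN, min_len)
  if (is.null(index)) index <- build_fragment_index(genome, k)
  ff <- maximal_fragments(seq, genome, index, k, strand)
  ff <- ff[len >= min_len]
  if (nrow(ff) == 0) return(NULL)
  best <- ff[len == max(len)]
  setorder(best, strand, sstart, qstart)  # "+" < "-" lexically
  top <- best[1]
  list(qstart = top$qstart, qend = top$qend, replicon = top$replicon,
       sstart = top$sstart, send = top$send, strand = top$strand,
       n_locations = nrow(unique(best[, .(replicon, sstart, strand)])))
}

#' Secondary fragment search in an unaligned flank
#'
#' Finds the longest exact match of the flank on the anchor's strand. The
#' match must be >= `min_seed` nt, lie within `max_span` nt of the anchor
#' (nearest fragment edges) and be the only genomic location of that
#' longest substring ("single positional" rule).
#'
#' @param flank_seq Unaligned flank sequence.
#' @param genome Named character vector.
#' @param anchor Primary fragment (list as from [find_primary_fragment()]).
#' @param min_seed Minimal secondary fragment length.
#' @param max_span Maximal genomic distance between the fragments.
#' @param index Optional precomputed fragment index.
#' @return Fragment list (read coordinates relative to the flank), or NULL.
#' @export
find_secondary_fragment <- function(flank_seq, genome, anchor,
                                    min_seed = 12L, max_span = 4000L,
                                    index = NULL) {
  if (nchar(flank_seq) < min_seed) return(NULL)
  hit <- longest_match(flank_seq, genome, min_seed, strand = anchor$strand,
                       index = index)
  if (is.null(hit)) return(NULL)
  if (hit$n_locations > 1) return(NULL)
  if (hit$replicon != anchor$replicon) return(NULL)
  gap <- max(anchor$sstart, hit$sstart) - min(anchor$send, hit$send)
  if (gap > max_span) return(NULL)
  hit
}

#' Combine two read fragments into a junction call
#'
#' A circularization junction exists iff the fragments are permuted: on the
#' plus strand the read-5' fragment lies genomically downstream of the
#' read-3' fragment (mirrored on the minus strand). Coordinates are
#' canonicalized by shifting the joint maximally toward lower genome
#' coordinates across identical bases.
#'
#' @param frag5,frag3 Fragments in read order (lists with replicon, sstart,
#'   send, strand).
#' @param genome Named character vector (for canonicalization).
#' @return List(replicon, strand, circ_start, circ_end) or NULL.
#' @export
call_junction <- function(frag5, frag3, genome) {
  if (frag5$replicon != frag3$replicon || frag5$strand != frag3$strand)
    return(NULL)
  if (frag5$strand == "+") {
    if (frag5$sstart < frag3$send) return(NULL)     # colinear / overlapping
    cs <- frag3$sstart
    ce <- frag5$send
  } else {
    if (frag3$sstart < frag5$send) return(NULL)
    cs <- frag5$sstart
    ce <- frag3$send
  }
  cc <- canonicalize_circle(genome, frag5$replicon, cs, ce)
  list(replicon = frag5$replicon, strand = frag5$strand,
       circ_start = cc[1], circ_end = cc[2])
}

#' Detect circularization junctions in a set of unmapped reads
#'
#' Per read: primary fragment, then a secondary fragment in the unaligned
#' 3' flank or, failing that, the 5' flank; a call is made when the
#' fragments are permuted. Reads containing N are skipped.
#'
#' @param reads Read table of unmapped reads.
#' @param genome Named character vector.
#' @param min_primary,min_seed,max_span Caller thresholds.
#' @param index Optional precomputed fragment index.
#' @return data.table: read_id, replicon, strand, circ_start, circ_end.
#' @export
detect_junctions <- function(reads, genome, min_primary = 20L,
                             min_seed = 12L, max_span = 4000L,
                             index = NULL) {
  empty <- data.table(read_id = character(), replicon = character(),
                      strand = character(), circ_start = integer(),
                      circ_end = integer())
  if (nrow(reads) == 0) return(empty)
  if (is.null(index))
    index <- build_fragment_index(genome, min(FRAG_SEED_LEN, min_seed))
  out <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (grepl("N", s, fixed = TRUE)) next
    prim <- find_primary_fragment(s, genome, min_primary, min_seed, index)
    if (is.null(prim)) next
    n <- nchar(s)
    jc <- NULL
    # 3' flank: primary is the read-5' fragment
    if (n - prim$qend >= min_seed) {
      flank <- substr(s, prim$qend + 1L, n)
      sec <- find_secondary_fragment(flank, genome, prim, min_seed,
                                     max_span, index)
      if (!is.null(sec)) jc <- call_junction(prim, sec, genome)
    }
    # 5' flank: primary is the read-3' fragment
    if (is.null(jc) && prim$qstart >= min_seed) {
      flank <- substr(s, 1L, prim$qstart)
      sec <- find_secondary_fragment(flank, genome, prim, min_seed,
                                     max_span, index)
      if (!is.null(sec)) jc <- call_junction(sec, prim, genome)
    }
    if (!is.null(jc))
      out[[length(out) + 1L]] <- data.table(
        read_id = reads$id[i], replicon = jc$replicon, strand = jc$strand,
        circ_start = jc$circ_start, circ_end = jc$circ_end)
  }
  if (!length(out)) return(empty)
  rbindlist(out)
}

#' Aggregate per-library junction calls into circRNA candidates
#'
#' Candidates must be supported by >= `min_reads` reads in >=
#' `min_libraries` of the eligible (CoIP) libraries; control-library counts
#' are reported but never qualify a candidate.
#'
#' @param calls Named list: library -> junction table from
#'   [detect_junctions()].
#' @param min_reads Minimal supporting reads per qualifying library.
#' @param min_libraries Minimal number of qualifying libraries.
#' @param eligible_libraries Libraries allowed to qualify a candidate.
#' @return data.table: replicon, strand, circ_start, circ_end, one count
#'   column per library, n_qualifying, kept.
#' @export
aggregate_candidates <- function(calls, min_reads = 10L,
                                 min_libraries = 3L,
                                 eligible_libraries = names(calls)) {
  all_libs <- names(calls)
  tabs <- rbindlist(lapply(all_libs, function(lib) {
    x <- calls[[lib]]
    if (nrow(x) == 0) return(NULL)
    x <- x[, .N, by = .(replicon, strand, circ_start, circ_end)]
    x[, library := lib]
    x
  }))
  if (is.null(tabs) || nrow(tabs) == 0)
    return(data.table(replicon = character(), strand = character(),
                      circ_start = integer(), circ_end = integer(),
                      n_qualifying = integer(), kept = logical()))
  wide <- dcast(tabs, replicon + strand + circ_start + circ_end ~ library,
                value.var = "N", fill = 0L)
  for (lib in setdiff(all_libs, names(wide))) wide[, (lib) := 0L]
  elig <- intersect(eligible_libraries, all_libs)
  wide[, n_qualifying := rowSums(.SD >= min_reads), .SDcols = elig]
  wide[, kept := n_qualifying >= min_libraries]
  setorder(wide, -kept, replicon, circ_start)
  wide[]
}
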