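# Crosslink-site assignment and metagene summaries. The crosslinked base
# is the nucleotide immediately 5' of the read start in transcript
# orientation (iCLIP cDNA truncation), so a deterministic position count
# replaces an HMM peak caller: every unique alignment contributes one
# crosslink at its upstream-adjacent base.

#' Assign crosslink sites from unique alignments
#'
#' Plus-strand alignment starting at p -> crosslink at p-1 (+); minus-
#' strand alignment ending at e (exclusive) -> crosslink at e (-).
#' Positions outside the replicon are dropped; sites below `min_count`
#' are removed.
#'
#' @param alignments Alignment table ([map_reads()]); unique hits only.
#' @param genome Named character vector.
#' @param min_count Minimal reads per retained site.
#' @param use_multiplicity Weight alignments by their `mult` column.
#' @return A stranded crosslink track (see [empty_track()]).
#' @export
assign_crosslinks <- function(alignments, genome, min_count = 1L,
                              use_multiplicity = FALSE) {
  track <- empty_track(genome)
  if (nrow(alignments) == 0) return(track)
  w <- if (use_multiplicity) alignments$mult else rep(1L, nrow(alignments))
  pos <- ifelse(alignments$strand == "+", alignments$start - 1L,
                alignments$end)
  L <- genome_lengths(genome)[alignments$replicon]
  ok <- pos >= 0 & pos < L
  dt <- data.table(replicon = alignments$replicon[ok],
                   strand = alignments$strand[ok],
                   pos = pos[ok], w = w[ok])
  agg <- dt[, .(n = sum(w)), by = .(replicon, strand, pos)]
  for (i in seq_len(nrow(agg)))
    track[[agg$replicon[i]]][[agg$strand[i]]][agg$pos[i] + 1L] <- agg$n[i]
  if (min_count > 1) {
    for (rn in names(track)) for (ori in c("+", "-")) {
      v <- track[[rn]][[ori]]
      v[v < min_count] <- 0L
      track[[rn]][[ori]] <- v
    }
  }
  track
}

#' Crosslink track as a site table
#' @param track Stranded track.
#' @return data.table: replicon, pos (0-based), strand, count.
#' @export
track_sites <- function(track) {
  rbindlist(lapply(names(track), function(rn)
    rbindlist(lapply(c("+", "-"), function(ori) {
      v <- track[[rn]][[ori]]
      nz <- which(v > 0)
      if (!length(nz)) return(NULL)
      data.table(replicon = rn, pos = nz - 1L, strand = ori,
                 count = v[nz])
    }))))
}

decile_of <- function(local, L) {
  # bin b covers local positions [floor((b-1)L/10), floor(bL/10))
  findInterval(local, floor((0:10) * L / 10), rightmost.closed = FALSE)
}

#' Crosslinks per gene-body decile
#'
#' Each gene is split into 10 equal bins ordered along the gene's 5'->3'
#' direction. Crosslinks on the gene's strand count as sense, on the
#' opposite strand as antisense; deciles are indexed in gene orientation
#' for BOTH orientations (an antisense RNA's 5' end thus appears in the
#' LAST decile of its host gene).
#'
#' @param track Crosslink track.
#' @param genes Gene table (optionally pre-filtered to one biotype).
#' @param orientation "sense" or "antisense".
#' @param normalize "raw" counts or "percent" of the orientation total.
#' @return data.table: decile (1..10), count (and percent).
#' @export
decile_profile <- function(track, genes,
                           orientation = c("sense", "antisense"),
                           normalize = c("raw", "percent")) {
  orientation <- match.arg(orientation)
  normalize <- match.arg(normalize)
  counts <- numeric(10)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    L <- g$end - g$start
    if (L < 10) next
    xstrand <- if (orientation == "sense") g$strand else
      setdiff(c("+", "-"), g$strand)
    v <- track[[g$replicon]][[xstrand]][(g$start + 1L):g$end]
    nz <- which(v > 0)
    if (!length(nz)) next
    local <- nz - 1L
    if (g$strand == "-") local <- L - 1L - local
    d <- decile_of(local, L)
    for (j in seq_along(nz)) counts[d[j]] <- counts[d[j]] + v[nz[j]]
  }
  out <- data.table(decile = 1:10, count = counts)
  if (normalize == "percent")
    out[, percent := if (sum(count) > 0) 100 * count / sum(count)
        else rep(NA_real_, .N)]
  out[]
}

#' Build artificial operon units from an operon table
#'
#' Each operon unit spans min(start)..max(end) of its member genes, which
#' must share replicon and strand.
#'
#' @param genes Gene table.
#' @param operon_table data.table gene_id, operon_id.
#' @return Gene-like table of operon units (gene_id = operon id).
#' @export
operon_units <- function(genes, operon_table) {
  gg <- merge(genes, operon_table, by = "gene_id",
              suffixes = c("", ".op"))
  if ("operon_id.op" %in% names(gg)) {
    gg[, operon_id := operon_id.op]
    gg[, operon_id.op := NULL]
  }
  if (nrow(gg) == 0)
    return(genes[0])
  bad <- gg[, .(ns = uniqueN(strand), nr = uniqueN(replicon)),
            by = operon_id][ns > 1 | nr > 1]
  if (nrow(bad))
    stop("strand- or replicon-discordant operon(s): ",
         paste(bad$operon_id, collapse = ", "))
  gg[, .(gene_id = operon_id[1], replicon = replicon[1],
         start = min(start), end = max(end), strand = strand[1],
         biotype = "operon", operon_id = operon_id[1]),
     by = operon_id][, operon_id := NULL][]
}

#' Decile profile over artificial operon units
#' @inheritParams decile_profile
#' @param operon_table data.table gene_id, operon_id.
#' @export
operon_profile <- function(track, genes, operon_table,
                           orientation = c("sense", "antisense"),
                           normalize = c("raw", "percent")) {
  units <- operon_units(genes, operon_table)
  decile_profile(track, units, orientation, normalize)
}

# offset of crosslink position p from a gene boundary, transcript
# orientation, no zero: start anchor -1|+1 flank the gene start; end
# anchor -1 is the last gene base, +1 the first downstream base
boundary_offset <- function(p, gene, anchor) {
  if (anchor == "start") {
    raw <- if (gene$strand == "+") p - gene$start else (gene$end - 1L) - p
    if (raw >= 0) raw + 1L else raw
  } else {
    raw <- if (gene$strand == "+") p - (gene$end - 1L) else gene$start - p
    if (raw <= 0) raw - 1L else raw
  }
}

#' Crosslink profile around gene starts or ends
#'
#' Offsets are measured in transcript orientation within +/- `window` nt of
#' the anchor; there is no offset 0 (for the start anchor, -1 is the base
#' upstream of the gene start and +1 the first gene base; for the end
#' anchor, -1 is the last gene base and +1 the first downstream base).
#' Sense-strand crosslinks only, unless `include_antisense`.
#'
#' @param track Crosslink track.
#' @param genes Gene table.
#' @param anchor "start" or "end".
#' @param window Half-window size in nt.
#' @param bin Bin width (1 or any divisor of `window`).
#' @param normalize "raw" or "percent" of the window total.
#' @param include_antisense Also count opposite-strand crosslinks.
#' @return data.table: offset (bin start, signed), count (and percent).
#' @export
boundary_profile <- function(track, genes, anchor = c("start", "end"),
                             window = 100L, bin = 1L,
                             normalize = c("raw", "percent"),
                             include_antisense = FALSE) {
  anchor <- match.arg(anchor)
  normalize <- match.arg(normalize)
  stopifnot(window > 0, window %% bin == 0)
  offsets <- c(-(window:1), 1:window)
  counts <- setNames(numeric(length(offsets)), offsets)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    L <- nchar_track(track, g$replicon)
    strands <- if (include_antisense) c("+", "-") else g$strand
    # genomic position for each offset
    for (off in offsets) {
      p <- genomic_at_offset(off, g, anchor)
      if (p < 0 || p >= L) next
      for (ori in strands)
        counts[as.character(off)] <- counts[as.character(off)] +
          track[[g$replicon]][[ori]][p + 1L]
    }
  }
  out <- data.table(offset = offsets, count = as.numeric(counts))
  if (bin > 1L) {
    out[, bin_id := ceiling(abs(offset) / bin) * sign(offset)]
    out <- out[, .(offset = min(offset), count = sum(count)), by = bin_id]
    out[, bin_id := NULL]
    setorder(out, offset)
  }
  if (normalize == "percent")
    out[, percent := if (sum(count) > 0) 100 * count / sum(count)
        else rep(NA_real_, .N)]
  out[]
}

nchar_track <- function(track, replicon) length(track[[replicon]][["+"]])

genomic_at_offset <- function(off, gene, anchor) {
  # inverse of boundary_offset
  raw <- if (off > 0) off - 1L else off
  if (anchor == "start") {
    if (gene$strand == "+") gene$start + raw else (gene$end - 1L) - raw
  } else {
    raw2 <- if (off < 0) off + 1L else off
    if (gene$strand == "+") (gene$end - 1L) + raw2 else gene$start - raw2
  }
}

#' Extract genomic windows around crosslink sites (motif input)
#'
#' For each selected site the `2*flank + 1` nt window centered on the site,
#' on the crosslink's strand; windows truncated by a replicon edge are
#' dropped.
#'
#' @param track Crosslink track.
#' @param genome Named character vector.
#' @param top_k Keep only the `top_k` highest-count sites (NULL = all).
#' @param min_count Keep only sites with at least this count.
#' @param flank Flank size in nt.
#' @return Named character vector of sequences (names: replicon:pos:strand).
#' @export
extract_motif_windows <- function(track, genome, top_k = NULL,
                                  min_count = 1L, flank = 10L) {
  stopifnot(flank >= 1)
  sites <- track_sites(track)
  sites <- sites[count >= min_count]
  if (!is.null(top_k)) {
    setorder(sites, -count, replicon, pos)
    sites <- head(sites, top_k)
  }
  if (nrow(sites) == 0) return(character())
  L <- genome_lengths(genome)[sites$replicon]
  ok <- sites$pos - flank >= 0 & sites$pos + flank + 1L <= L
  sites <- sites[ok]
  if (nrow(sites) == 0) return(character())
  out <- vapply(seq_len(nrow(sites)), function(i)
    seq_extract(genome, sites$replicon[i], sites$pos[i] - flank,
                sites$pos[i] + flank + 1L, sites$strand[i]),
    character(1))
  setNames(out, paste(sites$replicon, sites$pos, sites$strand, sep = ":"))
}
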