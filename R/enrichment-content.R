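# Gene-level TPM normalization, iCLIP/RNA-Seq coverage-ratio summaries,
# 2-fold enrichment calls at candidate loci, and nucleotide-content
# statistics of coding sequences and intergenic regions.

#' TPM-normalize gene read counts
#'
#' TPM_i = (c_i / l_i) / sum_j(c_j / l_j) * 1e6.
#'
#' @param counts Named numeric vector of raw read counts.
#' @param lengths Named numeric vector of gene lengths (nt), same genes.
#' @return data.table: gene_id, count, length, tpm.
#' @export
tpm_normalize <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  if (all(counts == 0)) stop("all-zero count vector cannot be normalized")
  rate <- counts / lengths
  tpm <- rate / sum(rate) * 1e6
  data.table(gene_id = if (is.null(names(counts)))
    as.character(seq_along(counts)) else names(counts),
    count = as.numeric(counts), length = as.numeric(lengths),
    tpm = tpm)
}

#' Intergenic regions: strand-blind complement of the gene union
#'
#' @param genes Gene table.
#' @param genome Named character vector.
#' @return data.table: replicon, start, end (0-based half-open), non-empty.
#' @export
igr_complement <- function(genes, genome) {
  out <- list()
  for (rn in names(genome)) {
    L <- nchar(genome[[rn]])
    gg <- genes[replicon == rn][order(start)]
    if (nrow(gg) == 0) {
      out[[rn]] <- data.table(replicon = rn, start = 0L, end = L)
      next
    }
    # merge overlapping gene intervals
    ms <- gg$start[1]; me <- gg$end[1]
    merged <- list()
    for (i in seq_len(nrow(gg))[-1]) {
      if (gg$start[i] <= me) me <- max(me, gg$end[i])
      else { merged[[length(merged) + 1L]] <- c(ms, me)
             ms <- gg$start[i]; me <- gg$end[i] }
    }
    merged[[length(merged) + 1L]] <- c(ms, me)
    m <- do.call(rbind, merged)
    gaps_start <- c(0L, m[, 2])
    gaps_end <- c(m[, 1], L)
    keep <- gaps_start < gaps_end
    if (any(keep))
      out[[rn]] <- data.table(replicon = rn, start = gaps_start[keep],
                              end = gaps_end[keep])
  }
  res <- rbindlist(out)
  if (nrow(res) == 0)
    res <- data.table(replicon = character(), start = integer(),
                      end = integer())
  res[]
}

strand_blind <- function(track, replicon) {
  track[[replicon]][["+"]] + track[[replicon]][["-"]]
}

scale_per_million <- function(v, total) if (total > 0) v / total * 1e6 else v

#' iCLIP/RNA-Seq per-position coverage ratio over regions
#'
#' Per-position (strand-blind) ratio iCLIP/RNA-Seq restricted to positions
#' with RNA-Seq coverage > 0; positions with zero RNA-Seq coverage are
#' counted separately. Both tracks are scaled to per-million coverage by
#' default. Quartiles use type-7 linear interpolation.
#'
#' @param iclip_cov,rnaseq_cov Stranded coverage tracks on one genome.
#' @param regions data.table replicon, start, end (e.g. [igr_complement()]
#'   output or CDS intervals).
#' @param normalize Scale both tracks to per-million before the ratio.
#' @return List: `ratios` (numeric vector), `summary` (median, q1, q3),
#'   `n_zero_rnaseq`, `n_positions`.
#' @export
coverage_ratio <- function(iclip_cov, rnaseq_cov, regions,
                           normalize = TRUE) {
  tot_i <- track_total(iclip_cov)
  tot_r <- track_total(rnaseq_cov)
  ratios <- list()
  n_zero <- 0L
  n_pos <- 0L
  for (rn in unique(regions$replicon)) {
    vi <- strand_blind(iclip_cov, rn)
    vr <- strand_blind(rnaseq_cov, rn)
    if (normalize) {
      vi <- scale_per_million(vi, tot_i)
      vr <- scale_per_million(vr, tot_r)
    }
    rr <- regions[replicon == rn]
    idx <- unlist(lapply(seq_len(nrow(rr)),
                         function(i) (rr$start[i] + 1L):rr$end[i]))
    n_pos <- n_pos + length(idx)
    zero <- vr[idx] == 0
    n_zero <- n_zero + sum(zero)
    ratios[[rn]] <- vi[idx][!zero] / vr[idx][!zero]
  }
  r <- unlist(ratios, use.names = FALSE)
  if (is.null(r)) r <- numeric()
  summ <- if (length(r))
    c(median = unname(median(r)),
      q1 = unname(quantile(r, 0.25, type = 7)),
      q3 = unname(quantile(r, 0.75, type = 7)))
  else c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
  list(ratios = r, summary = summ, n_zero_rnaseq = n_zero,
       n_positions = n_pos)
}

#' Call iCLIP enrichment at a locus
#'
#' Per iCLIP sample the peak (maximal per-base, strand-blind) coverage over
#' the locus is compared with the RNA-Seq peak. Rule A: fold change
#' iCLIP/RNA-Seq >= `fold`. Rule B: iCLIP peak >= `min_peak` while the
#' RNA-Seq peak is 0. The locus is enriched when any sample fires any rule.
#'
#' @param iclip_samples Named list of stranded coverage tracks.
#' @param rnaseq Stranded RNA-Seq coverage track.
#' @param locus List/row with replicon, start, end (0-based half-open).
#' @param fold Minimal fold change.
#' @param min_peak Minimal iCLIP peak for the zero-RNA-Seq rule.
#' @param normalize Scale all tracks to per-million first.
#' @return List: `enriched`, per-sample table (sample, iclip_peak,
#'   rnaseq_peak, fold, rule).
#' @export
call_enrichment <- function(iclip_samples, rnaseq, locus, fold = 2,
                            min_peak = 5, normalize = TRUE) {
  idx <- (locus$start + 1L):locus$end
  tot_r <- track_total(rnaseq)
  vr <- strand_blind(rnaseq, locus$replicon)
  if (normalize) vr <- scale_per_million(vr, tot_r)
  peak_r <- max(vr[idx])
  rows <- lapply(names(iclip_samples), function(nm) {
    vi <- strand_blind(iclip_samples[[nm]], locus$replicon)
    if (normalize)
      vi <- scale_per_million(vi, track_total(iclip_samples[[nm]]))
    peak_i <- max(vi[idx])
    fc <- if (peak_r > 0) peak_i / peak_r else Inf
    rule <- if (peak_r > 0 && fc >= fold) "fold"
            else if (peak_r == 0 && peak_i >= min_peak) "zero_rnaseq"
            else NA_character_
    data.table(sample = nm, iclip_peak = peak_i, rnaseq_peak = peak_r,
               fold = fc, rule = rule)
  })
  tab <- rbindlist(rows)
  list(enriched = any(!is.na(tab$rule)), samples = tab[])
}

longest_run <- function(seq, base = "A") {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(b == base)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Nucleotide-content statistics of coding sequences
#'
#' A fraction, A+G fraction and the longest poly(A) run on the coding
#' strand of each sequence; empty sequences are excluded.
#'
#' @param cds_sequences Named character vector of coding-strand DNA.
#' @return List: `table` (gene_id, length, a_frac, ag_frac, longest_a),
#'   `summary` (medians/quartiles and extreme gene ids).
#' @export
cds_content <- function(cds_sequences) {
  keep <- nchar(cds_sequences) > 0
  seqs <- cds_sequences[keep]
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs))
         else names(seqs)
  n <- nchar(seqs)
  nA <- nchar(seqs) - nchar(gsub("A", "", seqs, fixed = TRUE))
  nG <- nchar(seqs) - nchar(gsub("G", "", seqs, fixed = TRUE))
  runs <- vapply(seqs, longest_run, integer(1), USE.NAMES = FALSE)
  tab <- data.table(gene_id = ids, length = n, a_frac = nA / n,
                    ag_frac = (nA + nG) / n, longest_a = runs)
  q <- function(x) quantile(x, c(0.25, 0.5, 0.75), type = 7)
  summary <- list(
    n_cds = nrow(tab),
    a_frac = q(tab$a_frac),
    ag_frac = q(tab$ag_frac),
    longest_a = q(tab$longest_a),
    min_a = tab[which.min(a_frac), .(gene_id, a_frac)],
    max_a = tab[which.max(a_frac), .(gene_id, a_frac)],
    n_above_upper = sum(tab$longest_a > quantile(tab$longest_a, 0.75,
                                                 type = 7))
  )
  list(table = tab[], summary = summary)
}

#' Rank poly(A)/poly(T) runs inside intergenic regions
#'
#' Maximal runs of A (plus strand) and of T (reported as minus-strand
#' poly(A)) within each IGR, truncated at IGR edges, ranked by length
#' descending with coordinate tie-break.
#'
#' @param igrs data.table replicon, start, end.
#' @param genome Named character vector.
#' @param top_n Number of loci returned.
#' @param min_run Minimal run length reported.
#' @return data.table: replicon, start, end, strand, run_length.
#' @export
find_igr_polyA <- function(igrs, genome, top_n = 20L, min_run = 5L) {
  out <- list()
  for (i in seq_len(nrow(igrs))) {
    rn <- igrs$replicon[i]
    s0 <- igrs$start[i]
    seq <- seq_extract(genome, rn, s0, igrs$end[i])
    for (base in c("A", "T")) {
      m <- gregexpr(paste0(base, "{", min_run, ",}"), seq)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      out[[length(out) + 1L]] <- data.table(
        replicon = rn, start = s0 + as.integer(m) - 1L,
        end = s0 + as.integer(m) - 1L + len,
        strand = if (base == "A") "+" else "-", run_length = len)
    }
  }
  if (!length(out))
    return(data.table(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      run_length = integer()))
  res <- rbindlist(out)
  setorder(res, -run_length, replicon, start)
  head(res, top_n)
}

#' Extract coding-strand sequences for a gene table
#' @param genes Gene table.
#' @param genome Named character vector.
#' @return Named character vector (names = gene ids).
#' @export
gene_sequences <- function(genes, genome) {
  setNames(vapply(seq_len(nrow(genes)), function(i)
    seq_extract(genome, genes$replicon[i], genes$start[i], genes$end[i],
                genes$strand[i]), character(1)),
    genes$gene_id)
}
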