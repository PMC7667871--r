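# Independent oracles: brute force / direct enumeration, no shared code
# with the implementation paths they check.

# exhaustive ungapped Hamming scan over every offset and strand
oracle_map <- function(genome, seq, max_mismatches = 2L) {
  n <- nchar(seq)
  revcomp_chr <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
          collapse = "")
  }
  hits <- list()
  for (rn in names(genome)) {
    gch <- strsplit(genome[[rn]], "")[[1]]
    L <- length(gch)
    if (L < n) next
    noff <- L - n + 1L
    for (ori in c("+", "-")) {
      q <- if (ori == "+") seq else revcomp_chr(seq)
      qch <- strsplit(q, "")[[1]]
      mism <- integer(noff)
      for (j in seq_len(n))
        mism <- mism + (gch[j:(j + noff - 1L)] != qch[j])
      ok <- which(mism <= max_mismatches)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          replicon = rn, start = ok - 1L, strand = ori, nm = mism[ok])
    }
  }
  if (!length(hits)) return(list(status = "unmapped"))
  h <- do.call(rbind, hits)
  best <- h[h$nm == min(h$nm), , drop = FALSE]
  if (nrow(best) >= 2) return(list(status = "ambiguous"))
  list(status = "mapped", replicon = best$replicon, start = best$start,
       end = best$start + n, strand = best$strand, nm = best$nm)
}

# all exact occurrences of a pattern, 0-based starts, one strand
oracle_occurrences <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L
}

# enumerate every (split, start5, start3) junction explanation of a read:
# both fragments exact, same strand, permuted order, within max_span;
# returns canonical (circ_start, circ_end) pairs (left-shifted joints)
oracle_junctions <- function(seq, genome, min_primary = 20L,
                             min_seed = 12L, max_span = 4000L) {
  n <- nchar(seq)
  revcomp_chr <- function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
          collapse = "")
  shift_left <- function(s, cs, ce) {
    while (cs > 0 && substr(s, cs, cs) == substr(s, ce, ce)) {
      cs <- cs - 1L; ce <- ce - 1L
    }
    c(cs, ce)
  }
  out <- list()
  for (rn in names(genome)) {
    subj <- genome[[rn]]
    for (split in seq_len(n - 1L)) {
      l5 <- split; l3 <- n - split
      if (max(l5, l3) < min_primary || min(l5, l3) < min_seed) next
      p5 <- substr(seq, 1, split)
      p3 <- substr(seq, split + 1L, n)
      for (ori in c("+", "-")) {
        if (ori == "+") {
          s5 <- oracle_occurrences(p5, subj)
          s3 <- oracle_occurrences(p3, subj)
        } else {
          s5 <- oracle_occurrences(revcomp_chr(p5), subj)
          s3 <- oracle_occurrences(revcomp_chr(p3), subj)
        }
        for (a in s5) for (b in s3) {
          if (ori == "+") {
            if (a < b + l3) next                    # not permuted
            cs <- b; ce <- a + l5
          } else {
            if (b < a + l5) next
            cs <- a; ce <- b + l3
          }
          gap <- max(a, b) - min(a + l5, b + l3)
          if (gap > max_span) next
          cc <- shift_left(subj, cs, ce)
          out[[length(out) + 1L]] <- data.frame(
            replicon = rn, strand = ori, circ_start = cc[1],
            circ_end = cc[2])
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(replicon = character(), strand = character(),
                      circ_start = integer(), circ_end = integer()))
  unique(do.call(rbind, out))
}

# direct per-sequence content statistics via character vectors
oracle_content <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  run <- 0L; best <- 0L
  for (c in ch) {
    if (c == "A") { run <- run + 1L; best <- max(best, run) }
    else run <- 0L
  }
  list(a_frac = mean(ch == "A"), ag_frac = mean(ch %in% c("A", "G")),
       longest_a = best)
}

# longest common substring length between a read and a genome (both
# strands), by direct enumeration
oracle_lcs_len <- function(seq, genome) {
  n <- nchar(seq)
  revcomp_chr <- function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
          collapse = "")
  for (L in n:1) {
    starts <- seq_len(n - L + 1L)
    subs <- substring(seq, starts, starts + L - 1L)
    for (s in subs) for (rn in names(genome)) {
      if (grepl(s, genome[[rn]], fixed = TRUE) ||
          grepl(revcomp_chr(s), genome[[rn]], fixed = TRUE))
        return(L)
    }
  }
  0L
}
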