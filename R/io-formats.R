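#' @import data.table
#' @importFrom stats rpois runif setNames quantile median pchisq rgeom
#' @importFrom utils head tail
NULL

# Coordinate convention used package-wide: 0-based, half-open [start, end),
# positions on the plus strand of the named replicon. Conversion to/from
# 1-based formats (GFF3, R substr) happens ONLY in this file.

#' Read a genome FASTA into a named vector of uppercase DNA strings
#'
#' Sequences are uppercased and U is converted to T. Only A, C, G, T, N are
#' accepted after normalization. Duplicate headers are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per replicon.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ds <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  nm <- sub("\\s.*$", "", names(ds))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(ds)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in replicon(s): ",
         paste(nm[bad], collapse = ", "))
  if (any(nchar(seqs) == 0)) stop("empty sequence in FASTA: ", path)
  setNames(seqs, nm)
}

#' Write a genome to FASTA
#' @param genome Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), filepath = path, width = width)
  invisible(path)
}

#' Lengths of the replicons of a genome
#' @param genome Named character vector of DNA strings.
#' @export
genome_lengths <- function(genome) nchar(genome)

check_genome <- function(genome) {
  stopifnot(is.character(genome), length(genome) > 0,
            !is.null(names(genome)), !anyDuplicated(names(genome)))
  if (any(grepl("[^ACGTN]", genome))) stop("genome contains non-ACGTN bases")
  invisible(genome)
}

#' Extract genomic sequence (0-based, half-open, plus strand)
#'
#' @param genome Named character vector.
#' @param replicon Replicon name.
#' @param start,end 0-based half-open interval.
#' @param strand "+" returns the plus-strand slice; "-" its reverse complement.
#' @export
seq_extract <- function(genome, replicon, start, end, strand = "+") {
  L <- nchar(genome[[replicon]])
  stopifnot(start >= 0, end <= L, start < end)
  s <- substr(genome[[replicon]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# ---- gene annotation ---------------------------------------------------

BIOTYPES <- c("protein_coding", "rRNA", "tRNA", "other")

normalize_biotype <- function(x) {
  x <- ifelse(is.na(x) | !(x %in% BIOTYPES), "other", x)
  x
}

#' Read gene records from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. The biotype is read from the attribute named by
#' `biotype_key` (fallback "biotype"); unknown values become "other".
#' Records on replicons absent from `genome`, or extending past a replicon
#' end, are an error.
#'
#' @param path GFF3 path.
#' @param genome Named character vector (coordinate authority).
#' @param feature_types GFF3 `type` values to keep (default "gene").
#' @param biotype_key Attribute key carrying the biotype.
#' @return `data.table` with columns gene_id, replicon, start, end, strand,
#'   biotype, operon_id (NA unless present in attributes).
#' @export
read_gff3 <- function(path, genome, feature_types = "gene",
                      biotype_key = "gene_biotype") {
  check_genome(genome)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  md <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(keys) {
    for (k in keys) if (k %in% names(md)) return(as.character(md[[k]]))
    rep(NA_character_, length(gr))
  }
  ann <- data.table(
    gene_id  = pick(c("ID", "Name", "locus_tag")),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start    = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end      = GenomicRanges::end(gr),
    strand   = as.character(GenomicRanges::strand(gr)),
    biotype  = normalize_biotype(pick(c(biotype_key, "biotype"))),
    operon_id = pick("operon_id")
  )
  if (any(is.na(ann$gene_id)))
    ann[is.na(gene_id), gene_id := paste0("feature", .I)]
  unknown <- setdiff(unique(ann$replicon), names(genome))
  if (length(unknown))
    stop("GFF3 records on replicon(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  L <- genome_lengths(genome)[ann$replicon]
  if (any(ann$end > L) || any(ann$start < 0) || any(ann$start >= ann$end))
    stop("GFF3 record with coordinates outside its replicon")
  if (!all(ann$strand %in% c("+", "-")))
    stop("GFF3 gene records must be stranded (+/-)")
  ann[]
}

#' Write gene records to GFF3
#' @param annotation data.table as returned by [read_gff3()].
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @export
write_gff3 <- function(annotation, path, source = "exoclip") {
  attr9 <- paste0("ID=", annotation$gene_id,
                  ";gene_biotype=", annotation$biotype,
                  ifelse(is.na(annotation$operon_id), "",
                         paste0(";operon_id=", annotation$operon_id)))
  lines <- paste(annotation$replicon, source, "gene",
                 annotation$start + 1L, annotation$end, ".",
                 annotation$strand, ".", attr9, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read an operon table (TSV: gene_id, operon_id)
#' @param path TSV path with header columns gene_id, operon_id.
#' @export
read_operon_table <- function(path) {
  tb <- fread(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("gene_id", "operon_id") %in% names(tb)))
  tb[, .(gene_id, operon_id)]
}

# ---- FASTQ -------------------------------------------------------------

#' Read a FASTQ file (Phred+33) into a read table
#'
#' @param path FASTQ path.
#' @param library Optional library label stored with every read.
#' @return `data.table` with columns id, seq, qual, mult, library.
#' @export
read_fastq <- function(path, library = NA_character_) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0)
    return(data.table(id = character(), seq = character(),
                      qual = character(), mult = integer(),
                      library = character()))
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"),
    warning = function(w) {
      # Biostrings warns about dropped metadata columns on plain FASTQ
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.table(
    id = names(qs),
    seq = as.character(qs),
    qual = as.character(Biostrings::quality(qs)),
    mult = 1L,
    library = library
  )
}

#' Write a read table to FASTQ (Phred+33)
#' @param reads data.table with columns id, seq, qual.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) { file.create(path); return(invisible(path)) }
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  out <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual)
  writeLines(out, path)
  invisible(path)
}

# ---- coverage tracks & bedGraph ---------------------------------------

#' Create an all-zero stranded coverage track for a genome
#'
#' A track is a list: replicon -> list(`+` = integer vector, `-` = integer
#' vector), where element i of a vector is the count at 0-based position i-1.
#'
#' @param genome Named character vector.
#' @export
empty_track <- function(genome) {
  lapply(genome_lengths(genome), function(L)
    list(`+` = integer(L), `-` = integer(L)))
}

track_total <- function(track) {
  sum(vapply(track, function(r) sum(r[["+"]]) + sum(r[["-"]]), numeric(1)))
}

#' Write one strand of a coverage track as bedGraph
#'
#' Runs of equal values are merged, zero runs omitted; coordinates are
#' 0-based half-open as bedGraph requires.
#'
#' @param track Track as produced by [empty_track()] / [build_coverage()].
#' @param path Output path.
#' @param strand "+" or "-".
#' @export
write_bedgraph <- function(track, path, strand = "+") {
  con <- file(path, "w")
  on.exit(close(con))
  for (rep_name in names(track)) {
    v <- track[[rep_name]][[strand]]
    if (length(v) == 0) next
    r <- rle(as.numeric(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(rep_name, starts[keep], ends[keep], r$values[keep],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into per-replicon count vectors
#' @param path bedGraph path.
#' @param genome Genome giving replicon names and lengths.
#' @param strand Strand slot to fill ("+" or "-").
#' @return A track (other strand all zero).
#' @export
read_bedgraph <- function(path, genome, strand = "+") {
  track <- empty_track(genome)
  if (file.size(path) == 0) return(track)
  bg <- fread(path, header = FALSE,
              col.names = c("replicon", "start", "end", "value"))
  for (i in seq_len(nrow(bg))) {
    r <- bg$replicon[i]
    idx <- (bg$start[i] + 1L):bg$end[i]
    track[[r]][[strand]][idx] <- track[[r]][[strand]][idx] + bg$value[i]
  }
  track
}
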