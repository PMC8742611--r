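# Shared internal helpers and vocabulary constants.

# Column order of the contact TSV dialect; fixed so files are diff-stable.
CONTACT_COLUMNS <- c(
  "read_id", "rna_chrom", "rna_start", "rna_end", "rna_strand", "gene_id",
  "dna_chrom", "dna_start", "dna_end", "fraction", "replicate"
)

# Closed biotype vocabulary; anything else maps to "other".
GENE_BIOTYPES <- c("protein_coding", "lincRNA", "antisense", "snRNA",
                   "snoRNA", "other")

DECONV_STATUSES <- c("OK", "NO_BRIDGE", "MULTI_BRIDGE", "DNA_SHORT",
                     "DNA_LONG", "RNA_SHORT")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of a character vector of DNA strings ("" allowed).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Chromosome lengths of a genome object
#'
#' @param genome A `DNAStringSet` genome, a named numeric vector of lengths,
#'   or a simulated reference (list with `chrom_lengths`).
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is.list(genome) && !is.null(genome$chrom_lengths)) {
    genome$chrom_lengths
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stop("cannot extract chromosome lengths from this object")
  }
}

# 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_gr <- function(chrom, start, end, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand %||% "*"
  )
}

# Point (0-based position) -> width-1 GRanges.
points_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

pipeline_log <- function(fmt, ...) {
  if (isTRUE(getOption("redchip.verbose", TRUE))) message(sprintf(fmt, ...))
  invisible(NULL)
}

# Validate a contact data.frame against the container invariants.
validate_contacts <- function(contacts, lengths = NULL) {
  missing_cols <- setdiff(CONTACT_COLUMNS, names(contacts))
  if (length(missing_cols))
    stop("contact table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(contacts) == 0L) return(invisible(contacts))
  if (!all(contacts$fraction %in% c("IP", "input")))
    stop("unknown fraction value: ",
         paste(unique(setdiff(contacts$fraction, c("IP", "input"))), collapse = ", "))
  if (any(contacts$replicate < 1L)) stop("replicate must be >= 1")
  if (any(contacts$rna_start >= contacts$rna_end) ||
      any(contacts$dna_start >= contacts$dna_end))
    stop("degenerate interval: start must be < end")
  if (any(contacts$rna_start < 0L) || any(contacts$dna_start < 0L))
    stop("negative coordinate in contact table")
  if (!all(contacts$rna_strand %in% c("+", "-")))
    stop("rna_strand must be '+' or '-'")
  if (!is.null(lengths)) {
    bad <- contacts$rna_end > lengths[contacts$rna_chrom] |
      contacts$dna_end > lengths[contacts$dna_chrom]
    if (any(is.na(bad)) || any(bad))
      stop("contact coordinates exceed chromosome bounds")
  }
  invisible(contacts)
}
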