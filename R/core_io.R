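# Readers and writers for every on-disk format the pipeline touches.
# All internal coordinates are 0-based half-open; conversion happens only at
# format boundaries (GTF in, bedGraph out).

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; `N` is allowed. Chromosome names are taken up to
#' the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(x) == 0L) stop("empty FASTA: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate chromosome name in ", path, ": ",
         names(x)[duplicated(names(x))][1L])
  Biostrings::DNAStringSet(stats::setNames(toupper(as.character(x)), names(x)))
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  ids <- sub("/[12]$", "", ids)
  data.frame(id = ids, seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Read a pair of FASTQ files as mate pairs
#'
#' Mate ids must agree record-by-record after stripping a trailing `/1` or
#' `/2` suffix and any description after the first whitespace.
#'
#' @param path_r1,path_r2 FASTQ files for read 1 and read 2.
#' @return data.frame with columns `id, seq1, qual1, seq2, qual2`, in file
#'   order.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2))
    stop("mate files differ in record count: ", nrow(r1), " vs ", nrow(r2))
  if (nrow(r1)) {
    bad <- which(r1$id != r2$id)
    if (length(bad))
      stop("mate id mismatch at record ", bad[1L], ": '", r1$id[bad[1L]],
           "' vs '", r2$id[bad[1L]], "'")
  }
  data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Write paired FASTQ files
#'
#' @param reads data.frame with `id, seq1, qual1, seq2, qual2` (qualities
#'   optional; constant high quality is written when absent).
#' @param path_r1,path_r2 Output paths (gzipped when ending in `.gz`).
#' @export
write_fastq_pairs <- function(reads, path_r1, path_r2) {
  write_one <- function(ids, seqs, quals, path) {
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(ids))
      writeLines(paste(paste0("@", ids), seqs, "+", quals, sep = "\n"), con)
  }
  write_one(reads$id, reads$seq1, reads$qual1, path_r1)
  write_one(reads$id, reads$seq2, reads$qual2, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read a BED3/BED4 interval track
#'
#' Intervals are 0-based half-open (BED convention). Column 4, when present,
#' is kept as the interval label (chromatin state name, peak name, ...).
#'
#' @param path Path to a tab-separated BED file.
#' @return data.frame with columns `chrom, start, end, label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  out <- list(chrom = character(0), start = integer(0), end = integer(0),
              label = character(0))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("BED line ", ln, ": fewer than 3 tab-separated columns")
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      stop("BED line ", ln, ": non-integer coordinates")
    if (s >= e)
      stop("BED line ", ln, ": start (", s, ") must be < end (", e, ")")
    rows[[i]] <- list(chrom = f[1L], start = s, end = e,
                      label = if (length(f) >= 4L) f[4L] else "")
  }
  data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    label = vapply(rows, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
}

#' Write an interval track as BED
#'
#' @param track data.frame with `chrom, start, end` and optionally `label`.
#' @param path Output path.
#' @export
write_bed <- function(track, path) {
  cols <- track[, c("chrom", "start", "end")]
  if (!is.null(track$label) && any(nzchar(track$label)))
    cols$label <- track$label
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

map_biotype <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !(x %in% GENE_BIOTYPES)] <- "other"
  x
}

#' Read gene records from a GTF annotation
#'
#' Only `gene` features are used. GTF 1-based closed coordinates are
#' converted to the internal 0-based half-open convention. Biotypes outside
#' the closed vocabulary (protein_coding, lincRNA, antisense, snRNA, snoRNA)
#' map to `"other"`.
#'
#' @param path Path to a GTF file with `gene_id` and `gene_biotype`
#'   attributes.
#' @return data.frame with `gene_id, chrom, start, end, strand, biotype`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", path)
  ids <- gr$gene_id
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("gene feature without gene_id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate gene_id in ", path, ": ", ids[duplicated(ids)][1L])
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene without explicit strand in ", path)
  biotype <- gr$gene_biotype %||% gr$gene_type %||% rep(NA_character_, length(gr))
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    biotype = map_biotype(biotype),
    stringsAsFactors = FALSE
  )
}

#' Write gene records as GTF
#'
#' Inverse of [read_gtf_genes()]: internal 0-based half-open coordinates are
#' emitted as 1-based closed GTF `gene` features.
#'
#' @param genes data.frame as returned by [read_gtf_genes()].
#' @param path Output path.
#' @export
write_gtf_genes <- function(genes, path) {
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";',
                   genes$gene_id, genes$biotype)
  lines <- paste(genes$chrom, "redchip", "gene", genes$start + 1L, genes$end,
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the contact TSV
#'
#' Tab-separated, one header line, fixed column order
#' `read_id, rna_chrom, rna_start, rna_end, rna_strand, gene_id, dna_chrom,
#' dna_start, dna_end, fraction, replicate`. Round-trip is identity.
#'
#' @param contacts Contact data.frame.
#' @param path File path.
#' @return `read_contacts` returns the contact data.frame.
#' @export
write_contacts <- function(contacts, path) {
  validate_contacts(contacts)
  utils::write.table(contacts[, CONTACT_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(
    path, stringsAsFactors = FALSE,
    colClasses = c(
      read_id = "character", rna_chrom = "character", rna_start = "integer",
      rna_end = "integer", rna_strand = "character", gene_id = "character",
      dna_chrom = "character", dna_start = "integer", dna_end = "integer",
      fraction = "character", replicate = "integer"
    )
  )
  if (!identical(names(x), CONTACT_COLUMNS))
    stop("unexpected contact TSV columns in ", path)
  validate_contacts(x)
  x
}

#' Export binned part coverage as bedGraph
#'
#' Counts DNA or RNA part midpoints in fixed-size bins tiling each
#' chromosome; zero bins are omitted (sparse bedGraph convention) and the
#' last bin of a chromosome is truncated at the chromosome end.
#'
#' @param contacts Contact data.frame.
#' @param genome Genome object accepted by [chrom_lengths()].
#' @param which `"dna"` or `"rna"`: which part of the chimera to profile.
#' @param path Output path.
#' @param bin_bp Bin size in base pairs (default 1000).
#' @export
export_coverage_bedgraph <- function(contacts, genome, which = c("dna", "rna"),
                                     path, bin_bp = 1000L) {
  which <- match.arg(which)
  lens <- chrom_lengths(genome)
  if (length(lens) == 0L) stop("empty genome")
  chrom <- contacts[[paste0(which, "_chrom")]]
  mid <- (contacts[[paste0(which, "_start")]] +
            contacts[[paste0(which, "_end")]]) %/% 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="redchip_%s_coverage"', which),
             con)
  if (nrow(contacts) > 0L) {
    bin <- mid %/% bin_bp
    tab <- table(chrom, bin)
    for (cn in names(lens)) {
      if (!cn %in% rownames(tab)) next
      cnt <- tab[cn, ]
      cnt <- cnt[cnt > 0L]
      if (!length(cnt)) next
      b <- as.integer(names(cnt))
      o <- order(b)
      b <- b[o]; cnt <- cnt[o]
      writeLines(paste(cn, b * bin_bp,
                       pmin((b + 1L) * bin_bp, lens[[cn]]),
                       as.integer(cnt), sep = "\t"), con)
    }
  }
  invisible(path)
}
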