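# Map deconvolved parts to the genome, assign RNA parts to genes, remove
# PCR duplicates and emit the contact table.

#' Extract alignable parts from a deconvolution result
#'
#' @param reads data.frame from [deconvolve_library()]`$reads`.
#' @return Long data.frame `read_id, part, seq` over OK reads only.
#' @export
ok_parts <- function(reads) {
  ok <- reads[reads$status == "OK", , drop = FALSE]
  data.frame(
    read_id = rep(ok$read_id, 2L),
    part = rep(c("dna", "rna"), each = nrow(ok)),
    seq = c(ok$dna_seq, ok$rna_seq),
    stringsAsFactors = FALSE
  )
}

#' Exact-match fixture aligner
#'
#' Searches each part sequence on both genome strands for exact occurrences.
#' A part is `unique` iff it occurs exactly once genome-wide; parts occurring
#' more than once are reported with their first occurrence and
#' `unique = FALSE`; absent parts yield no row. RNA parts are searched in
#' transcript-sense orientation, so a forward-strand hit means strand `"+"`.
#' Intended for synthetic fixtures; production data enters through
#' [ingest_alignments()].
#'
#' @param parts data.frame `read_id, part, seq` (see [ok_parts()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @return data.frame `read_id, part, chrom, start, end, strand, unique`
#'   with 0-based half-open coordinates.
#' @export
align_exact <- function(parts, genome) {
  empty <- data.frame(read_id = character(0), part = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      unique = logical(0), stringsAsFactors = FALSE)
  if (nrow(parts) == 0L) return(empty)
  clean <- grepl("^[ACGT]+$", parts$seq)
  useq <- unique(parts$seq[clean])
  if (length(useq) == 0L) return(empty)
  w <- min(nchar(useq))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(useq, 1L, w)))
  occ <- vector("list", length(useq))  # per seq: list of c(chrom, start0, strand)
  lens <- nchar(useq)
  chrom_names <- names(genome)
  for (ci in seq_along(genome)) {
    subject <- genome[[ci]]
    clen <- length(subject)
    fwd_str <- as.character(subject)
    rev_str <- as.character(Biostrings::reverseComplement(subject))
    for (strand in c("+", "-")) {
      sstr <- if (strand == "+") fwd_str else rev_str
      mi <- Biostrings::matchPDict(pd, if (strand == "+") subject else
        Biostrings::reverseComplement(subject))
      starts <- Biostrings::startIndex(mi)
      for (si in seq_along(useq)) {
        s <- starts[[si]]
        if (is.null(s) || length(s) == 0L) next
        l <- lens[si]
        s <- s[s + l - 1L <= clen]
        if (!length(s)) next
        hit <- substring(sstr, s, s + l - 1L) == useq[si]
        s <- s[hit]
        for (pos in s) {
          start0 <- if (strand == "+") pos - 1L else clen - (pos - 1L) - l
          occ[[si]] <- c(occ[[si]],
                         list(list(chrom = chrom_names[ci], start = start0,
                                   strand = strand)))
        }
      }
    }
  }
  n_occ <- vapply(occ, length, 0L)
  idx <- match(parts$seq, useq)
  keep <- which(clean & !is.na(idx) & n_occ[idx] > 0L)
  if (!length(keep)) return(empty)
  first <- lapply(occ, function(o) if (length(o)) o[[1L]] else NULL)
  data.frame(
    read_id = parts$read_id[keep],
    part = parts$part[keep],
    chrom = vapply(first[idx[keep]], `[[`, "", "chrom"),
    start = vapply(first[idx[keep]], `[[`, 0L, "start"),
    end = vapply(first[idx[keep]], `[[`, 0L, "start") + nchar(parts$seq[keep]),
    strand = vapply(first[idx[keep]], `[[`, "", "strand"),
    unique = n_occ[idx[keep]] == 1L,
    stringsAsFactors = FALSE
  )
}

#' Ingest externally produced alignments
#'
#' Thin coordinates-only ingestion: either a SAM text file (no CIGAR-aware
#' processing; the aligned span is taken as the read length) or a 6-column
#' TSV with header `read_id, chrom, start, end, strand, unique`. Unmapped
#' records are skipped; secondary/supplementary records and records with
#' mapping quality 0 are kept with `unique = FALSE`.
#'
#' @param path Alignment file.
#' @param part_kind `"rna"` or `"dna"` label for the resulting parts.
#' @param chroms Optional character vector of known reference names; an
#'   alignment to any other name is an error.
#' @return data.frame as from [align_exact()].
#' @export
ingest_alignments <- function(path, part_kind = c("rna", "dna"),
                              chroms = NULL) {
  part_kind <- match.arg(part_kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_sam <- any(grepl("^@(HD|SQ|RG|PG|CO)\t", lines)) ||
    (length(lines) && length(strsplit(lines[[1L]], "\t")[[1L]]) >= 11L &&
       !grepl("\t(chrom|start)\t?", lines[[1L]]))
  if (is_sam) {
    body <- lines[!grepl("^@", lines)]
    rows <- lapply(body, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 11L) stop("malformed SAM line: ", substr(ln, 1, 60))
      flag <- as.integer(f[2L])
      if (bitwAnd(flag, 4L) > 0L) return(NULL)  # unmapped
      mapq <- as.integer(f[5L])
      secondary <- bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L
      start0 <- as.integer(f[4L]) - 1L
      list(read_id = f[1L], chrom = f[3L], start = start0,
           end = start0 + nchar(f[10L]),
           strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
           unique = !secondary && mapq > 0L)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    out <- data.frame(
      read_id = vapply(rows, `[[`, "", "read_id"),
      part = rep(part_kind, length(rows)),
      chrom = vapply(rows, `[[`, "", "chrom"),
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      unique = vapply(rows, `[[`, TRUE, "unique"),
      stringsAsFactors = FALSE
    )
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "chrom", "start", "end", "strand", "unique")
    if (!all(need %in% names(x)))
      stop("alignment TSV needs columns: ", paste(need, collapse = ", "))
    out <- data.frame(read_id = as.character(x$read_id),
                      part = rep(part_kind, nrow(x)),
                      chrom = as.character(x$chrom),
                      start = as.integer(x$start), end = as.integer(x$end),
                      strand = as.character(x$strand),
                      unique = as.logical(x$unique),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(chroms)) {
    bad <- setdiff(unique(out$chrom), chroms)
    if (length(bad)) stop("unknown reference name: ", bad[1L])
  }
  out
}

#' Assign RNA-part alignments to genes
#'
#' A candidate gene must overlap the alignment interval on the same strand
#' (an antisense transcript must itself be annotated to be counted). Among
#' candidates the largest overlap wins; ties go to the smallest gene, then
#' lexicographic `gene_id`. Gene-body rule: any overlap with the annotated
#' gene interval counts.
#'
#' @param rna_alns data.frame with `chrom, start, end, strand` (0-based
#'   half-open).
#' @param genes Gene data.frame (see [read_gtf_genes()]).
#' @return Character vector of gene ids (`"unassigned"` when no candidate).
#' @export
assign_gene <- function(rna_alns, genes) {
  n <- nrow(rna_alns)
  out <- rep("unassigned", n)
  if (n == 0L || nrow(genes) == 0L) return(out)
  q <- intervals_to_gr(rna_alns$chrom, rna_alns$start, rna_alns$end,
                       rna_alns$strand)
  s <- intervals_to_gr(genes$chrom, genes$start, genes$end, genes$strand)
  ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  if (length(ov) == 0L) return(out)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ow <- GenomicRanges::width(IRanges::pintersect(q[qh], s[sh]))
  gw <- genes$end[sh] - genes$start[sh]
  o <- order(qh, -ow, gw, genes$gene_id[sh])
  qh <- qh[o]; sh <- sh[o]
  best <- !duplicated(qh)
  out[qh[best]] <- genes$gene_id[sh[best]]
  out
}

#' Pair part alignments into a contact table
#'
#' A contact is emitted iff both parts of a read align uniquely. The RNA
#' part is assigned to a gene with [assign_gene()]; PCR duplicates --
#' records identical in `(rna_chrom, rna_start, dna_chrom, dna_start,
#' fraction, replicate)` (5' coordinate key, the standard proximity-ligation
#' duplicate definition) -- collapse to one record.
#'
#' @param rna_alns,dna_alns Part alignments (see [align_exact()]).
#' @param genes Gene data.frame.
#' @param fraction `"IP"` or `"input"`.
#' @param replicate Replicate number (>= 1).
#' @param read_ids Optional character vector of all deconvolved OK read ids,
#'   used for the conservation statistics; defaults to the ids seen in
#'   either alignment set.
#' @return Contact data.frame with a `stats` attribute recording
#'   `n_reads, n_both_unique, n_duplicate, n_contacts` (conservation:
#'   `n_reads = n_contacts + rejected`).
#' @export
build_contacts <- function(rna_alns, dna_alns, genes, fraction, replicate,
                           read_ids = NULL) {
  stopifnot(fraction %in% c("IP", "input"), replicate >= 1L)
  rna <- rna_alns[rna_alns$part == "rna" & rna_alns$unique, , drop = FALSE]
  dna <- dna_alns[dna_alns$part == "dna" & dna_alns$unique, , drop = FALSE]
  if (is.null(read_ids))
    read_ids <- union(rna_alns$read_id, dna_alns$read_id)
  m <- merge(rna, dna, by = "read_id", suffixes = c("_rna", "_dna"))
  contacts <- data.frame(
    read_id = m$read_id,
    rna_chrom = m$chrom_rna, rna_start = m$start_rna, rna_end = m$end_rna,
    rna_strand = m$strand_rna,
    gene_id = rep("unassigned", nrow(m)),
    dna_chrom = m$chrom_dna, dna_start = m$start_dna, dna_end = m$end_dna,
    fraction = rep(fraction, nrow(m)),
    replicate = rep(as.integer(replicate), nrow(m)),
    stringsAsFactors = FALSE
  )
  if (nrow(contacts)) {
    contacts$gene_id <- assign_gene(
      data.frame(chrom = contacts$rna_chrom, start = contacts$rna_start,
                 end = contacts$rna_end, strand = contacts$rna_strand,
                 stringsAsFactors = FALSE),
      genes)
    key <- paste(contacts$rna_chrom, contacts$rna_start, contacts$dna_chrom,
                 contacts$dna_start, contacts$fraction, contacts$replicate,
                 sep = "\r")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    contacts <- contacts[!dup, , drop = FALSE]
    rownames(contacts) <- NULL
  } else {
    n_dup <- 0L
  }
  stats <- c(n_reads = length(read_ids), n_both_unique = nrow(m),
             n_duplicate = n_dup, n_contacts = nrow(contacts))
  pipeline_log("contacts [%s rep %d]: %d OK reads -> %d both-unique, %d dup removed, %d contacts",
               fraction, replicate, stats[["n_reads"]],
               stats[["n_both_unique"]], stats[["n_duplicate"]],
               stats[["n_contacts"]])
  attr(contacts, "stats") <- stats
  contacts
}

#' Per-gene total contact counts
#'
#' @param contacts Contact data.frame.
#' @return Named integer vector over assigned genes (unassigned contacts are
#'   excluded but still count toward the table total).
#' @export
gene_contact_counts <- function(contacts) {
  g <- contacts$gene_id[contacts$gene_id != "unassigned"]
  if (!length(g)) return(stats::setNames(integer(0), character(0)))
  tab <- table(g)
  stats::setNames(as.integer(tab), names(tab))
}
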