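# Split chimeric read pairs into a genomic DNA tag and an RNA-derived part
# by locating the bridge adapter, applying the chemistry constraints of the
# protocol: the DNA side is a short restriction tag cut at a fixed distance
# from the bridge (MmeI-type, ~18-22 bp), the RNA side is a cDNA synthesized
# from the bridge with template switching at the RNA 5' end (non-templated
# G's). Layout assumed for read 1:
#
#   [DNA tag][bridge][template-switch G's][RNA cDNA ...]
#
# Read 2 is ignored by default (single-side deconvolution).

#' Bridge/chemistry configuration
#'
#' @param bridge_seq Bridge adapter sequence as it appears in read 1
#'   (required; A/C/G/T only).
#' @param max_mismatches Substitutions tolerated when locating the bridge
#'   (default 1; no indels).
#' @param dna_tag_min,dna_tag_max Accepted DNA tag length window in bp
#'   (defaults 18 and 22, the MmeI-type cut-length window).
#' @param rna_min_len Minimum RNA part length in bp after trimming
#'   (default 14).
#' @param gggg_trim Trim the leading run of up to 4 G's on the RNA cDNA, the
#'   template-switch artifact (default TRUE).
#' @return A `bridge_config` list.
#' @export
bridge_config <- function(bridge_seq, max_mismatches = 1L, dna_tag_min = 18L,
                          dna_tag_max = 22L, rna_min_len = 14L,
                          gggg_trim = TRUE) {
  bridge_seq <- toupper(bridge_seq)
  if (!nzchar(bridge_seq) || grepl("[^ACGT]", bridge_seq))
    stop("bridge_seq must be a nonempty A/C/G/T string")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  if (dna_tag_min > dna_tag_max || dna_tag_min < 0L)
    stop("invalid DNA tag length window")
  if (rna_min_len < 0L) stop("rna_min_len must be >= 0")
  structure(list(
    bridge_seq = bridge_seq,
    max_mismatches = as.integer(max_mismatches),
    dna_tag_min = as.integer(dna_tag_min),
    dna_tag_max = as.integer(dna_tag_max),
    rna_min_len = as.integer(rna_min_len),
    gggg_trim = isTRUE(gggg_trim)
  ), class = "bridge_config")
}

#' 20-nt bridge sequence used in examples and simulations
#'
#' The deconvolution algorithm is independent of the oligo identity; this
#' fixed 20-mer is the sequence embedded by the bundled simulator.
#'
#' @return A length-1 character vector.
#' @export
example_bridge <- function() "GTTGGAGTTCGGTGTGAGGC"

#' Locate the bridge adapter in a read
#'
#' Returns every 0-based offset `p` where the Hamming distance between
#' `substr(seq, p + 1, p + nchar(bridge))` and `bridge` is at most
#' `max_mismatches`. Substitution-only model (no indels); an `N` in the read
#' counts as a mismatch.
#'
#' @param seq Read sequence (may contain N).
#' @param bridge Bridge sequence (A/C/G/T).
#' @param max_mismatches Allowed substitutions.
#' @return Integer vector of 0-based match offsets (possibly empty).
#' @export
find_bridge <- function(seq, bridge, max_mismatches = 0L) {
  seq <- toupper(seq)
  bridge <- toupper(bridge)
  if (nchar(bridge) > nchar(seq)) return(integer(0))
  m <- Biostrings::matchPattern(bridge, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatches,
                                with.indels = FALSE, fixed = TRUE)
  s <- Biostrings::start(m)
  # drop partial matches hanging over either end of the read
  s <- s[s >= 1L & s + nchar(bridge) - 1L <= nchar(seq)]
  s - 1L
}

# Vectorized engine shared by split_read_pair() and deconvolve_library().
deconvolve_pairs <- function(pairs, cfg) {
  stopifnot(inherits(cfg, "bridge_config"))
  n <- nrow(pairs)
  empty_counts <- stats::setNames(integer(length(DECONV_STATUSES)),
                                  DECONV_STATUSES)
  if (n == 0L) {
    return(list(
      reads = data.frame(read_id = character(0), status = character(0),
                         dna_seq = character(0), rna_seq = character(0),
                         stringsAsFactors = FALSE),
      status_counts = empty_counts
    ))
  }
  seqs <- toupper(pairs$seq1)
  L <- nchar(cfg$bridge_seq)
  nh <- integer(n)
  p <- rep(NA_integer_, n)
  long <- nchar(seqs) >= L
  if (any(long)) {
    mi <- Biostrings::vmatchPattern(cfg$bridge_seq,
                                    Biostrings::DNAStringSet(seqs[long]),
                                    max.mismatch = cfg$max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
    sl <- Biostrings::startIndex(mi)
    ns <- nchar(seqs[long])
    # drop partial matches hanging over either end of the read
    sl <- mapply(function(s, n) {
      if (is.null(s)) integer(0) else s[s >= 1L & s + L - 1L <= n]
    }, sl, ns, SIMPLIFY = FALSE)
    cnt <- lengths(sl)
    nh[long] <- cnt
    first <- rep(NA_integer_, length(cnt))
    first[cnt == 1L] <- vapply(sl[cnt == 1L], `[`, 0L, 1L)
    p[long] <- first - 1L
  }
  status <- rep("OK", n)
  dna <- character(n)
  rna <- character(n)
  one <- nh == 1L
  if (any(one)) {
    dna[one] <- substr(seqs[one], 1L, p[one])
    cdna <- substr(seqs[one], p[one] + L + 1L, nchar(seqs[one]))
    # Template-switch artifact: trim min(run, 4) leading G's of the cDNA,
    # then report the RNA part in transcript-sense orientation.
    if (cfg$gggg_trim) cdna <- sub("^G{1,4}", "", cdna)
    rna[one] <- revcomp(cdna)
  }
  # First failing rule wins; later assignments overwrite, so apply in
  # reverse priority: RNA_SHORT < DNA_LONG < DNA_SHORT < MULTI < NO_BRIDGE.
  status[one & nchar(rna) < cfg$rna_min_len] <- "RNA_SHORT"
  status[one & nchar(dna) > cfg$dna_tag_max] <- "DNA_LONG"
  status[one & nchar(dna) < cfg$dna_tag_min] <- "DNA_SHORT"
  status[nh >= 2L] <- "MULTI_BRIDGE"
  status[nh == 0L] <- "NO_BRIDGE"
  bad <- status != "OK"
  dna[bad] <- ""
  rna[bad] <- ""
  counts <- table(factor(status, levels = DECONV_STATUSES))
  list(
    reads = data.frame(read_id = pairs$id, status = status, dna_seq = dna,
                       rna_seq = rna, stringsAsFactors = FALSE),
    status_counts = stats::setNames(as.integer(counts), DECONV_STATUSES)
  )
}

#' Deconvolve a single read pair
#'
#' Applies the read-1 layout `[DNA tag][bridge][RNA cDNA]`: the bridge is
#' located with [find_bridge()]; the DNA tag is the prefix before the bridge;
#' the RNA part is everything after it, leading-G trimmed (template-switch
#' artifact) and reverse-complemented to transcript sense. Status is assigned
#' by the first failing rule in fixed order: NO_BRIDGE, MULTI_BRIDGE,
#' DNA_SHORT/DNA_LONG, RNA_SHORT, else OK. Read 2 is ignored (single-side
#' deconvolution).
#'
#' @param id Read id.
#' @param seq1,seq2 Mate sequences (`seq2` unused, kept for symmetry).
#' @param cfg A [bridge_config()].
#' @return One-row data.frame `read_id, status, dna_seq, rna_seq`.
#' @export
split_read_pair <- function(id, seq1, seq2 = NULL, cfg) {
  deconvolve_pairs(data.frame(id = id, seq1 = seq1,
                              stringsAsFactors = FALSE), cfg)$reads
}

#' Deconvolve a whole paired-end library
#'
#' @param fastq_r1 Path to the R1 FASTQ, or a pairs data.frame as returned
#'   by [read_fastq_pairs()] (then `fastq_r2` is ignored).
#' @param fastq_r2 Path to the R2 FASTQ.
#' @param cfg A [bridge_config()].
#' @return List with `reads` (one row per input pair: `read_id, status,
#'   dna_seq, rna_seq`) and `status_counts` (named integer vector over all
#'   statuses; sums to the number of input pairs).
#' @export
deconvolve_library <- function(fastq_r1, fastq_r2 = NULL, cfg) {
  pairs <- if (is.data.frame(fastq_r1)) fastq_r1 else
    read_fastq_pairs(fastq_r1, fastq_r2)
  res <- deconvolve_pairs(pairs, cfg)
  pipeline_log("deconvolve: %d pairs in, %d OK (%s)",
               nrow(pairs), res$status_counts[["OK"]],
               paste(sprintf("%s=%d", names(res$status_counts),
                             res$status_counts), collapse = ", "))
  res
}

#' Write the per-read deconvolution table and status statistics
#'
#' @param result List from [deconvolve_library()].
#' @param parts_path Output TSV for per-read parts.
#' @param stats_path Optional output TSV for the status counts.
#' @export
write_deconvolved <- function(result, parts_path, stats_path = NULL) {
  utils::write.table(result$reads, parts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(stats_path)) {
    utils::write.table(
      data.frame(status = names(result$status_counts),
                 n = as.integer(result$status_counts)),
      stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(parts_path)
}
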