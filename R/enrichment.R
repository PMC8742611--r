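# IP/input enrichment analyses: cis windows, fold changes, enriched-RNA
# calling, chromatin-state breakdowns, peak metaprofiles, rank statistics
# and the nonparametric group/overlap tests.
#
# Normalization convention for every IP/input ratio: by total contacts in
# the fraction (proportion ratio), the minimal depth correction; it is
# invariant under rescaling either library.

#' Cis window of a gene
#'
#' The genomic interval spanning the gene body extended by `window_bp` on
#' each side (gene included), clamped to the chromosome.
#'
#' @param gene One-row data.frame or list with `start`, `end`.
#' @param window_bp Window half-width in bp (default 1e6).
#' @param chrom_length Length of the parent chromosome.
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
cis_window <- function(gene, window_bp = 1e6, chrom_length) {
  stopifnot(window_bp >= 0)
  c(start = max(0, gene$start - window_bp),
    end = min(chrom_length, gene$end + window_bp))
}

#' Count cis and trans contacts of one gene
#'
#' Over contacts assigned to the gene: cis contacts have the DNA part
#' overlapping the cis window on the parent chromosome; trans contacts have
#' the DNA part on a nonparental chromosome. Parental-chromosome contacts
#' outside the window belong to neither.
#'
#' @param gene One-row gene data.frame (needs `gene_id, chrom, start, end`).
#' @param contacts Contact data.frame.
#' @param window_bp Cis window half-width (default 1e6).
#' @return Integer `c(cis, trans)`.
#' @export
count_cis_trans <- function(gene, contacts, window_bp = 1e6) {
  x <- contacts[contacts$gene_id == gene$gene_id, , drop = FALSE]
  if (nrow(x) == 0L) return(c(cis = 0L, trans = 0L))
  parent <- x$dna_chrom == gene$chrom
  in_win <- parent &
    x$dna_end > (gene$start - window_bp) &
    x$dna_start < (gene$end + window_bp)
  c(cis = sum(in_win), trans = sum(!parent))
}

#' Depth-normalized IP/input fold change
#'
#' `FC = (count_ip / total_ip) / (count_in / total_in)`; undefined (NA, gene
#' excluded downstream) when either count is below `min_count`, a filter
#' against ratio blow-up at low coverage. Vectorized over counts.
#'
#' @param count_ip,count_in Per-gene contact counts.
#' @param total_ip,total_in Library totals (must be > 0).
#' @param min_count Minimum count per fraction for FC to be defined
#'   (default 10).
#' @return Numeric fold changes with NA where undefined.
#' @export
fold_change <- function(count_ip, total_ip, count_in, total_in,
                        min_count = 10L) {
  if (any(total_ip <= 0) || any(total_in <= 0))
    stop("library totals must be > 0")
  fc <- (count_ip / total_ip) / (count_in / total_in)
  fc[count_ip < min_count | count_in < min_count] <- NA_real_
  fc
}

#' Enriched-RNA call across replicates
#'
#' TRUE iff the fold change is defined and strictly greater than `threshold`
#' in every replicate (the published rule: fold enrichment > 1.3 in both
#' replicates; replicates are never merged for calling).
#'
#' @param fc_per_replicate Numeric vector of per-replicate fold changes.
#' @param threshold Fold-change threshold (default 1.3).
#' @return Logical scalar.
#' @export
call_enriched <- function(fc_per_replicate, threshold = 1.3) {
  length(fc_per_replicate) >= 1L &&
    !anyNA(fc_per_replicate) &&
    all(fc_per_replicate > threshold)
}

# Midpoint-based chromatin-state assignment; segmentation must be
# non-overlapping per chromosome. Returns a character vector (NA when the
# midpoint falls outside every segment).
assign_state <- function(chrom, mid, segmentation) {
  out <- rep(NA_character_, length(chrom))
  if (!length(chrom) || nrow(segmentation) == 0L) return(out)
  q <- points_to_gr(chrom, mid)
  s <- intervals_to_gr(segmentation$chrom, segmentation$start,
                       segmentation$end)
  ov <- GenomicRanges::findOverlaps(q, s, select = "first",
                                    ignore.strand = TRUE)
  hit <- !is.na(ov)
  out[hit] <- segmentation$label[ov[hit]]
  out
}

#' Percentage of a gene's contacts per chromatin state
#'
#' The DNA-part midpoint determines the state. Percentages are over
#' classified contacts and sum to 100; contacts whose midpoint falls outside
#' every segment are excluded from the denominator and reported via the
#' `n_unclassified` attribute.
#'
#' @param contacts Contact data.frame.
#' @param segmentation Interval track with state labels (non-overlapping).
#' @param gene_id Optional gene id to restrict to.
#' @param scope `"genome"` (all contacts of the gene) or `"cis_window"`
#'   (DNA part overlapping the gene's cis window; requires `genes`).
#' @param genes Gene data.frame (needed for `scope = "cis_window"`).
#' @param window_bp Cis window half-width.
#' @return data.frame `state, count, percent` with attributes
#'   `n_classified` and `n_unclassified`.
#' @export
state_percentages <- function(contacts, segmentation, gene_id = NULL,
                              scope = c("genome", "cis_window"),
                              genes = NULL, window_bp = 1e6) {
  scope <- match.arg(scope)
  x <- contacts
  if (!is.null(gene_id)) x <- x[x$gene_id == gene_id, , drop = FALSE]
  if (scope == "cis_window") {
    if (is.null(gene_id) || is.null(genes))
      stop("cis_window scope needs gene_id and genes")
    g <- genes[genes$gene_id == gene_id, , drop = FALSE]
    if (nrow(g) != 1L) stop("unknown gene_id: ", gene_id)
    x <- x[x$dna_chrom == g$chrom &
             x$dna_end > (g$start - window_bp) &
             x$dna_start < (g$end + window_bp), , drop = FALSE]
  }
  st <- assign_state(x$dna_chrom, (x$dna_start + x$dna_end) %/% 2L,
                     segmentation)
  classified <- !is.na(st)
  states <- sort(unique(segmentation$label))
  tab <- table(factor(st[classified], levels = states))
  n_cl <- sum(classified)
  out <- data.frame(
    state = states,
    count = as.integer(tab),
    percent = if (n_cl > 0L) 100 * as.integer(tab) / n_cl else
      rep(NA_real_, length(states)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_classified") <- n_cl
  attr(out, "n_unclassified") <- sum(!classified)
  out
}

#' Per-state IP/input contact ratio
#'
#' For each chromatin state, the depth-normalized ratio
#' `(count_ip / total_ip) / (count_in / total_in)` of contacts whose DNA-part
#' midpoint falls in that state. States with no input contacts are NA.
#'
#' @param contacts_ip,contacts_input Contact data.frames (nonempty).
#' @param segmentation Labeled, non-overlapping interval track.
#' @return data.frame `state, count_ip, count_input, ratio`.
#' @export
state_ratio_ip_input <- function(contacts_ip, contacts_input, segmentation) {
  if (nrow(contacts_ip) == 0L || nrow(contacts_input) == 0L)
    stop("both contact tables must be nonempty")
  states <- sort(unique(segmentation$label))
  cnt <- function(x) {
    st <- assign_state(x$dna_chrom, (x$dna_start + x$dna_end) %/% 2L,
                       segmentation)
    as.integer(table(factor(st[!is.na(st)], levels = states)))
  }
  ip <- cnt(contacts_ip)
  inp <- cnt(contacts_input)
  ratio <- (ip / nrow(contacts_ip)) / (inp / nrow(contacts_input))
  ratio[inp == 0L] <- NA_real_
  data.frame(state = states, count_ip = ip, count_input = inp,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Metaprofile of DNA parts around peaks
#'
#' For every contact, the signed distance of the DNA-part midpoint to the
#' nearest peak center on the same chromosome (ties broken toward the
#' upstream peak); distances within `[-flank_bp, flank_bp]` are binned into
#' `n_bins` equal bins (odd, so a center bin exists). Counts are also
#' reported as contacts per million total contacts.
#'
#' @param contacts Contact data.frame.
#' @param peaks Interval track of peaks (nonempty).
#' @param flank_bp Flank in bp (default 10000).
#' @param n_bins Odd number of bins (default 41).
#' @return data.frame `bin_start, bin_end, bin_mid, count, cpm` where the
#'   bin coordinates are distances to the peak center.
#' @export
peak_metaprofile <- function(contacts, peaks, flank_bp = 10000L,
                             n_bins = 41L) {
  if (nrow(peaks) == 0L) stop("empty peak set")
  if (n_bins %% 2L == 0L) stop("n_bins must be odd")
  centers <- split((peaks$start + peaks$end) %/% 2L, peaks$chrom)
  centers <- lapply(centers, sort)
  mid <- (contacts$dna_start + contacts$dna_end) %/% 2L
  dist <- rep(NA_real_, nrow(contacts))
  for (cn in names(centers)) {
    sel <- which(contacts$dna_chrom == cn)
    if (!length(sel)) next
    cs <- centers[[cn]]
    i <- findInterval(mid[sel], cs)
    left <- ifelse(i >= 1L, cs[pmax(i, 1L)], NA_real_)
    right <- ifelse(i < length(cs), cs[pmin(i + 1L, length(cs))], NA_real_)
    dl <- mid[sel] - left    # >= 0 or NA
    dr <- mid[sel] - right   # <= 0 or NA
    use_left <- !is.na(dl) & (is.na(dr) | dl <= abs(dr))
    dist[sel] <- ifelse(use_left, dl, dr)
  }
  breaks <- seq(-flank_bp, flank_bp, length.out = n_bins + 1L)
  inside <- !is.na(dist) & dist >= -flank_bp & dist <= flank_bp
  bin <- findInterval(dist[inside], breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  total <- max(nrow(contacts), 1L)
  data.frame(
    bin_start = breaks[-(n_bins + 1L)],
    bin_end = breaks[-1L],
    bin_mid = (breaks[-(n_bins + 1L)] + breaks[-1L]) / 2,
    count = counts,
    cpm = 1e6 * counts / total
  )
}

#' Two-sided rank-sum (Mann-Whitney U) test
#'
#' Exact null by full enumeration of all group assignments when both groups
#' have at most 8 values (ties handled through midranks); tie-corrected
#' normal approximation otherwise. The statistic is the rank-sum U of the
#' first group.
#'
#' @param x,y Numeric vectors (each needs >= 3 non-NA values).
#' @param exact Force (TRUE) or forbid (FALSE) enumeration; default chooses
#'   by group size.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  na <- length(x)
  nb <- length(y)
  if (na < 3L || nb < 3L) stop("each group needs >= 3 defined values")
  if (is.null(exact)) exact <- na <= 8L && nb <= 8L
  r <- rank(c(x, y))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  if (exact) {
    idx <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    eps <- sqrt(.Machine$double.eps)
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    list(statistic = u, p_value = p, method = "exact enumeration")
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "normal approximation")
  }
}

#' Compare fold-change distributions between two RNA biotypes
#'
#' Applies [rank_sum_test()] to the per-gene mean fold change (over defined
#' replicates) of two biotype groups from an enrichment table.
#'
#' @param results data.frame with a `biotype` column and `fc_rep*` columns
#'   (see [enrichment_table()]).
#' @param biotype_a,biotype_b Biotype labels to compare.
#' @return List with `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
biotype_fc_test <- function(results, biotype_a, biotype_b) {
  fc_cols <- grep("^fc_rep", names(results), value = TRUE)
  if (!length(fc_cols)) stop("results lacks fc_rep* columns")
  fc <- rowMeans(results[, fc_cols, drop = FALSE])
  a <- fc[results$biotype == biotype_a & !is.na(fc)]
  b <- fc[results$biotype == biotype_b & !is.na(fc)]
  res <- rank_sum_test(a, b)
  c(res[c("statistic", "p_value")],
    list(n_a = length(a), n_b = length(b), method = res$method))
}

#' Pairwise biotype comparisons with FDR control
#'
#' Runs [biotype_fc_test()] for every requested biotype pair and reports
#' Benjamini-Hochberg adjusted p values alongside the raw ones.
#'
#' @param results Enrichment table (see [enrichment_table()]).
#' @param pairs Two-column matrix or data.frame of biotype pairs; default:
#'   all unordered pairs of biotypes present with at least 3 genes.
#' @return data.frame `biotype_a, biotype_b, n_a, n_b, statistic, p_value,
#'   p_adjusted`.
#' @export
biotype_fc_tests <- function(results, pairs = NULL) {
  if (is.null(pairs)) {
    fc_cols <- grep("^fc_rep", names(results), value = TRUE)
    fc <- rowMeans(results[, fc_cols, drop = FALSE])
    tab <- table(results$biotype[!is.na(fc)])
    bts <- names(tab)[tab >= 3L]
    if (length(bts) < 2L) stop("fewer than two biotypes with >= 3 defined FCs")
    pairs <- t(utils::combn(bts, 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- biotype_fc_test(results, pairs[i, 1L], pairs[i, 2L])
    data.frame(biotype_a = pairs[i, 1L], biotype_b = pairs[i, 2L],
               n_a = r$n_a, n_b = r$n_b, statistic = r$statistic,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' One-sided overlap (hypergeometric) test of two gene lists
#'
#' Fisher's exact test, upper tail: the probability of drawing at least the
#' observed overlap when `|A|` genes are sampled without replacement from a
#' universe containing `|B|` marked genes.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Size of the gene universe (must be at least
#'   `|A union B|`).
#' @return List with `overlap`, `p_value`, `expected`.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (universe_size < length(union(set_a, set_b)))
    stop("universe smaller than the union of the sets")
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_b), universe_size - length(set_b),
                     length(set_a), lower.tail = FALSE)
  list(overlap = k, p_value = p,
       expected = length(set_a) * length(set_b) / universe_size)
}

#' Rank RNAs by total contact count
#'
#' @param counts Named integer vector from [gene_contact_counts()].
#' @param total Denominator for the contact share (defaults to
#'   `sum(counts)`; pass the table total to include unassigned contacts).
#' @return data.frame `gene_id, n_contacts, share` sorted by descending
#'   count, ties by gene id.
#' @export
rank_rnas <- function(counts, total = sum(counts)) {
  if (!length(counts))
    return(data.frame(gene_id = character(0), n_contacts = integer(0),
                      share = numeric(0), stringsAsFactors = FALSE))
  o <- order(-counts, names(counts))
  data.frame(gene_id = names(counts)[o],
             n_contacts = as.integer(counts[o]),
             share = as.numeric(counts[o]) / total,
             stringsAsFactors = FALSE)
}

# Per-gene cis or trans contact counts for one contact table.
count_mode_by_gene <- function(contacts, genes, mode, window_bp) {
  g <- genes[match(contacts$gene_id, genes$gene_id), , drop = FALSE]
  assigned <- !is.na(g$gene_id)
  sel <- if (mode == "cis") {
    assigned & contacts$dna_chrom == g$chrom &
      contacts$dna_end > (g$start - window_bp) &
      contacts$dna_start < (g$end + window_bp)
  } else {
    assigned & contacts$dna_chrom != g$chrom
  }
  tab <- table(factor(contacts$gene_id[sel], levels = genes$gene_id))
  stats::setNames(as.integer(tab), genes$gene_id)
}

#' Per-gene IP/input enrichment table
#'
#' For each annotated gene and each replicate, counts cis (or trans)
#' contacts in the replicate-matched IP and input tables, computes the
#' depth-normalized fold change, and calls a gene enriched when the fold
#' change exceeds `threshold` in every replicate ([call_enriched()]). A
#' pooled-count `fc_merged` is reported as a descriptive extra only.
#'
#' @param ip,input Lists of contact data.frames, one per replicate,
#'   replicate-matched by position.
#' @param genes Gene data.frame.
#' @param mode `"cis"` or `"trans"`.
#' @param window_bp Cis window half-width (default 1e6).
#' @param threshold Fold-change threshold (default 1.3).
#' @param min_count Minimum count filter (default 10).
#' @return data.frame with one row per gene: counts and `fc_rep*` per
#'   replicate, `fc_merged`, and the `enriched` flag.
#' @export
enrichment_table <- function(ip, input, genes, mode = c("cis", "trans"),
                             window_bp = 1e6, threshold = 1.3,
                             min_count = 10L) {
  mode <- match.arg(mode)
  if (is.data.frame(ip)) ip <- list(ip)
  if (is.data.frame(input)) input <- list(input)
  if (length(ip) != length(input))
    stop("need one input table per IP replicate")
  n_rep <- length(ip)
  out <- data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
                    stringsAsFactors = FALSE)
  fc_mat <- matrix(NA_real_, nrow(genes), n_rep)
  pooled_ip <- 0L; pooled_in <- 0L
  pooled_tip <- 0L; pooled_tin <- 0L
  for (k in seq_len(n_rep)) {
    c_ip <- count_mode_by_gene(ip[[k]], genes, mode, window_bp)
    c_in <- count_mode_by_gene(input[[k]], genes, mode, window_bp)
    t_ip <- nrow(ip[[k]])
    t_in <- nrow(input[[k]])
    fc_mat[, k] <- fold_change(c_ip, t_ip, c_in, t_in, min_count)
    out[[sprintf("count_ip_rep%d", k)]] <- unname(c_ip)
    out[[sprintf("count_input_rep%d", k)]] <- unname(c_in)
    pooled_ip <- pooled_ip + c_ip; pooled_in <- pooled_in + c_in
    pooled_tip <- pooled_tip + t_ip; pooled_tin <- pooled_tin + t_in
  }
  for (k in seq_len(n_rep)) out[[sprintf("fc_rep%d", k)]] <- fc_mat[, k]
  out$fc_merged <- unname(fold_change(pooled_ip, pooled_tip, pooled_in,
                                      pooled_tin, min_count))
  out$enriched <- apply(fc_mat, 1L, call_enriched, threshold = threshold)
  attr(out, "params") <- list(mode = mode, window_bp = window_bp,
                              threshold = threshold, min_count = min_count,
                              n_replicates = n_rep)
  out
}
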