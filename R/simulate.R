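# Fully synthetic experiment generator: toy genome, strand-annotated genes
# of several biotypes, a tiling chromatin-state segmentation, peaks inside a
# designated state, ground-truth contact tables with injected IP enrichment,
# and paired FASTQ reads with embedded bridge adapters.
#
# The IP fraction is simulated by importance reweighting of the
# input-generating distribution: the sampling weight of a (gene, DNA
# position) draw is multiplied by the enrichment factor e when the gene is
# designated enriched AND the DNA position falls in the designated chromatin
# state; rejection sampling then draws exactly from the renormalized
# distribution. This creates precisely the proportion-ratio signal the
# fold-change estimator targets.

#' Simulation configuration
#'
#' @param seed Integer seed; every stage derives its RNG stream from it.
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length in bp.
#' @param n_genes Number of genes (packed without overlap).
#' @param biotype_mix Named probabilities over biotypes.
#' @param gene_length_range Min/max gene length in bp.
#' @param state_labels Chromatin-state labels; the first is the designated
#'   (protein-bound) state unless `target_state` says otherwise.
#' @param target_state The designated state carrying peaks and the injected
#'   IP enrichment.
#' @param state_block_bp Size of the tiling state blocks in bp.
#' @param n_peaks Number of peaks placed inside the designated state.
#' @param n_contacts_per_fraction Contacts per fraction per replicate.
#' @param n_replicates Replicates per fraction.
#' @param enriched_gene_fraction Fraction of genes carrying the injected
#'   enrichment.
#' @param enrichment_factor Injected IP/input enrichment factor `e` (> 0).
#' @param p_cis Probability a contact is placed on the parent chromosome.
#' @param cis_decay_scale Scale (bp) of the symmetric exponential distance
#'   decay for cis placement.
#' @param rna_frag_range Min/max RNA fragment length in bp.
#' @param dna_tag_range Min/max DNA tag length in bp (MmeI window).
#' @param noise Probability that a read pair loses its bridge.
#' @param sub_rate Per-base substitution probability in the reads.
#' @param ts_gggg Simulate 0-3 non-templated template-switch G's.
#' @param expr_sdlog sdlog of the log-normal expression weights.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2e6,
                       n_genes = 200L,
                       biotype_mix = c(protein_coding = 0.70, lincRNA = 0.14,
                                       antisense = 0.08, snRNA = 0.04,
                                       snoRNA = 0.04),
                       gene_length_range = c(2000L, 10000L),
                       state_labels = c("Polycomb", "PoisedPromoter",
                                        "Enhancer", "Insulator", "Quiescent"),
                       target_state = state_labels[1L],
                       state_block_bp = 250000L,
                       n_peaks = 40L,
                       n_contacts_per_fraction = 50000L,
                       n_replicates = 2L,
                       enriched_gene_fraction = 0.05,
                       enrichment_factor = 2,
                       p_cis = 0.75,
                       cis_decay_scale = 25000,
                       rna_frag_range = c(25L, 75L),
                       dna_tag_range = c(18L, 22L),
                       noise = 0,
                       sub_rate = 0,
                       ts_gggg = TRUE,
                       expr_sdlog = 1) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), biotype_mix = biotype_mix,
              gene_length_range = as.integer(gene_length_range),
              state_labels = state_labels, target_state = target_state,
              state_block_bp = as.integer(state_block_bp),
              n_peaks = as.integer(n_peaks),
              n_contacts_per_fraction = as.integer(n_contacts_per_fraction),
              n_replicates = as.integer(n_replicates),
              enriched_gene_fraction = enriched_gene_fraction,
              enrichment_factor = enrichment_factor, p_cis = p_cis,
              cis_decay_scale = cis_decay_scale,
              rna_frag_range = as.integer(rna_frag_range),
              dna_tag_range = as.integer(dna_tag_range),
              noise = noise, sub_rate = sub_rate, ts_gggg = isTRUE(ts_gggg),
              expr_sdlog = expr_sdlog)
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length > 0L, cfg$n_genes >= 0L,
            abs(sum(cfg$biotype_mix) - 1) < 1e-6,
            all(names(cfg$biotype_mix) %in% GENE_BIOTYPES),
            cfg$gene_length_range[1L] <= cfg$gene_length_range[2L],
            cfg$target_state %in% cfg$state_labels,
            cfg$enrichment_factor > 0, cfg$p_cis >= 0, cfg$p_cis <= 1,
            cfg$noise >= 0, cfg$noise <= 1, cfg$sub_rate >= 0,
            cfg$sub_rate <= 1, cfg$cis_decay_scale > 0)
  structure(cfg, class = "sim_config")
}

random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Fraction of k-mers occurring more than once across the given sequences.
kmer_dup_fraction <- function(seqs, k = 20L) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (!length(kmers)) return(0)
  mean(duplicated(kmers) | duplicated(kmers, fromLast = TRUE))
}

#' Simulate a reference: genome, genes, states, peaks
#'
#' The genome is random sequence, rejection-sampled so that fewer than 1%
#' of its 20-mers are duplicated (keeps the exact-match fixture aligner
#' near-lossless). Genes are packed without overlap by slotting each
#' chromosome; chromatin states tile the genome in fixed-size blocks with
#' cycling labels; peaks sit inside the designated state.
#'
#' @param cfg A [sim_config()].
#' @param sequences Generate genome sequences (TRUE). Analysis-scale studies
#'   that never touch reads can skip them (FALSE) and receive only
#'   chromosome lengths.
#' @return A `redchip_reference` list: `genome` (DNAStringSet or NULL),
#'   `chrom_lengths`, `genes`, `states`, `peaks`, `cfg`.
#' @export
simulate_reference <- function(cfg, sequences = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chrom_names)

  # genes: one slot per gene, gene placed at a random offset inside it
  n_per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1L)))
  max_len <- cfg$gene_length_range[2L]
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    np <- n_per[ci]
    if (np == 0L) next
    slot <- cfg$chrom_length %/% np
    if (slot <= max_len + 1L)
      stop("cannot place ", cfg$n_genes, " genes of up to ", max_len,
           " bp in this genome; reduce n_genes or gene length")
    glen <- sample(seq(cfg$gene_length_range[1L], max_len), np,
                   replace = TRUE)
    off <- vapply(glen, function(l) sample.int(slot - l, 1L), 0L)
    start <- (seq_len(np) - 1L) * slot + off
    gene_rows[[ci]] <- data.frame(
      gene_id = sprintf("G%04d", gi + seq_len(np)),
      chrom = chrom_names[ci],
      start = start,
      end = start + glen,
      strand = sample(c("+", "-"), np, replace = TRUE),
      biotype = sample(names(cfg$biotype_mix), np, replace = TRUE,
                       prob = cfg$biotype_mix),
      stringsAsFactors = FALSE
    )
    gi <- gi + np
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               biotype = character(0), stringsAsFactors = FALSE)

  # chromatin states: tiling blocks with cycling labels across chromosomes
  state_rows <- list()
  lab_i <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    nb <- ceiling(cfg$chrom_length / cfg$state_block_bp)
    s <- (seq_len(nb) - 1L) * cfg$state_block_bp
    e <- pmin(s + cfg$state_block_bp, cfg$chrom_length)
    labs <- cfg$state_labels[(lab_i + seq_len(nb) - 1L) %%
                               length(cfg$state_labels) + 1L]
    lab_i <- lab_i + nb
    state_rows[[ci]] <- data.frame(chrom = chrom_names[ci], start = s,
                                   end = e, label = labs,
                                   stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, state_rows)

  # peaks: uniform within designated-state blocks, 200 bp wide
  des <- states[states$label == cfg$target_state, , drop = FALSE]
  if (nrow(des) == 0L) stop("no designated-state blocks")
  peaks <- if (cfg$n_peaks > 0L) {
    seg <- sample.int(nrow(des), cfg$n_peaks, replace = TRUE,
                      prob = des$end - des$start)
    center <- des$start[seg] + 100L +
      floor(stats::runif(cfg$n_peaks) * (des$end[seg] - des$start[seg] - 200L))
    data.frame(chrom = des$chrom[seg], start = center - 100L,
               end = center + 100L,
               label = sprintf("peak%03d", seq_len(cfg$n_peaks)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               label = character(0), stringsAsFactors = FALSE)
  }

  genome <- NULL
  if (sequences) {
    for (attempt in 1:5) {
      seqs <- vapply(lens, random_chrom, "")
      if (kmer_dup_fraction(seqs) < 0.01) break
      if (attempt == 5L) stop("could not sample a genome with unique-ish 20-mers")
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chrom_names))
  }

  structure(list(genome = genome, chrom_lengths = lens, genes = genes,
                 states = states, peaks = peaks, cfg = cfg),
            class = "redchip_reference")
}

# Laplace CDF centered at 0 with scale s.
plaplace <- function(q, s) ifelse(q < 0, 0.5 * exp(q / s),
                                  1 - 0.5 * exp(-q / s))

# Per-gene mass of the cis placement distribution (Laplace around the gene
# midpoint) falling inside designated-state segments on the parent
# chromosome.
designated_cis_mass <- function(genes, states, cfg) {
  des <- states[states$label == cfg$target_state, , drop = FALSE]
  vapply(seq_len(nrow(genes)), function(i) {
    m <- (genes$start[i] + genes$end[i]) / 2
    seg <- des[des$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(seg) == 0L) return(0)
    sum(plaplace(seg$end - m, cfg$cis_decay_scale) -
          plaplace(seg$start - m, cfg$cis_decay_scale))
  }, 0)
}

# Fast membership test: is position `pos` on chromosome `chrom` inside a
# designated-state segment?
designated_lookup <- function(states, target_state) {
  des <- states[states$label == target_state, , drop = FALSE]
  by_chrom <- split(des[, c("start", "end")], des$chrom)
  by_chrom <- lapply(by_chrom, function(d) d[order(d$start), , drop = FALSE])
  function(chrom, pos) {
    out <- logical(length(pos))
    for (cn in unique(chrom)) {
      d <- by_chrom[[cn]]
      sel <- chrom == cn
      if (is.null(d)) next
      i <- findInterval(pos[sel], d$start)
      out[sel] <- i >= 1L & pos[sel] < d$end[pmax(i, 1L)]
    }
    out
  }
}

draw_contact_table <- function(cfg, ref, weights, enriched, fraction,
                               replicate, in_designated) {
  n <- cfg$n_contacts_per_fraction
  genes <- ref$genes
  ng <- nrow(genes)
  lens <- ref$chrom_lengths
  chroms <- names(lens)
  e <- cfg$enrichment_factor
  emax <- max(e, 1)
  boost_on <- fraction == "IP" && e != 1
  cols <- list()
  got <- 0L
  while (got < n) {
    m <- as.integer(ceiling((n - got) * (if (boost_on) 2.6 else 1.05)) + 64L)
    gi <- sample.int(ng, m, replace = TRUE, prob = weights)
    glen <- genes$end[gi] - genes$start[gi]
    flen <- pmin(sample(seq(cfg$rna_frag_range[1L], cfg$rna_frag_range[2L]),
                        m, replace = TRUE), glen)
    rs <- genes$start[gi] + floor(stats::runif(m) * (glen - flen + 1))
    re <- rs + flen
    tag <- sample(seq(cfg$dna_tag_range[1L], cfg$dna_tag_range[2L]), m,
                  replace = TRUE)
    iscis <- stats::runif(m) < cfg$p_cis
    dchrom <- genes$chrom[gi]
    dmid <- numeric(m)
    if (any(iscis)) {
      delta <- stats::rexp(sum(iscis), rate = 1 / cfg$cis_decay_scale) *
        sample(c(-1, 1), sum(iscis), replace = TRUE)
      dmid[iscis] <- round((rs[iscis] + re[iscis]) / 2 + delta)
    }
    if (any(!iscis)) {
      nt <- sum(!iscis)
      if (length(chroms) < 2L) stop("trans placement needs >= 2 chromosomes")
      parent <- match(dchrom[!iscis], chroms)
      pick <- 1L + floor(stats::runif(nt) * (length(chroms) - 1L))
      pick <- pick + (pick >= parent)  # skip the parent chromosome
      dchrom[!iscis] <- chroms[pick]
      dmid[!iscis] <- floor(stats::runif(nt) * lens[pick])
    }
    half <- tag %/% 2L
    dmid <- pmin(pmax(dmid, half + 1), lens[dchrom] - half - 1)
    ds <- as.integer(round(dmid) - half)
    de <- ds + tag
    if (boost_on) {
      boosted <- enriched[gi] & in_designated(dchrom, round(dmid))
      w <- ifelse(boosted, e, 1) / emax
      keep <- stats::runif(m) < w
    } else {
      keep <- rep(TRUE, m)
    }
    if (!any(keep)) next
    cols[[length(cols) + 1L]] <- data.frame(
      gene_i = gi[keep], rna_start = as.integer(rs[keep]),
      rna_end = as.integer(re[keep]), dna_chrom = dchrom[keep],
      dna_start = ds[keep], dna_end = as.integer(de[keep]),
      stringsAsFactors = FALSE
    )
    got <- got + sum(keep)
  }
  d <- do.call(rbind, cols)[seq_len(n), , drop = FALSE]
  data.frame(
    read_id = sprintf("%s_r%d_%07d", fraction, replicate, seq_len(n)),
    rna_chrom = genes$chrom[d$gene_i],
    rna_start = d$rna_start,
    rna_end = d$rna_end,
    rna_strand = genes$strand[d$gene_i],
    gene_id = genes$gene_id[d$gene_i],
    dna_chrom = d$dna_chrom,
    dna_start = d$dna_start,
    dna_end = d$dna_end,
    fraction = rep(fraction, n),
    replicate = rep(as.integer(replicate), n),
    stringsAsFactors = FALSE
  )
}

#' Simulate ground-truth contact tables for IP and input fractions
#'
#' Input contacts draw a source gene proportional to log-normal expression
#' weights, an RNA fragment uniform within the gene, and a DNA position
#' that is cis (parent chromosome, symmetric exponential distance decay)
#' with probability `p_cis`, else uniform on a random nonparental
#' chromosome. The IP fraction reweights (gene, DNA position) draws by the
#' enrichment factor when the gene is enriched and the DNA position lies in
#' the designated state. Enriched genes are those whose cis placement mass
#' is best covered by the designated state, so their recoverable cis fold
#' change approximates the injected factor. Replicates are drawn
#' independently.
#'
#' @param cfg A [sim_config()].
#' @param ref Reference from [simulate_reference()].
#' @return List with `tables` (named `"IP_1", "input_1", ...`) and
#'   `gene_truth` (per gene: biotype, expression weight, designated-state
#'   mass, enriched flag, injected factor).
#' @export
simulate_contacts <- function(cfg, ref) {
  stopifnot(inherits(ref, "redchip_reference"))
  genes <- ref$genes
  ng <- nrow(genes)
  set.seed(cfg$seed + 1L)
  weights <- stats::rlnorm(ng, meanlog = 0, sdlog = cfg$expr_sdlog)
  mass <- designated_cis_mass(genes, ref$states, cfg)
  n_enr <- round(cfg$enriched_gene_fraction * ng)
  enr_idx <- utils::head(order(-mass, genes$gene_id), n_enr)
  enriched <- seq_len(ng) %in% enr_idx
  in_designated <- designated_lookup(ref$states, cfg$target_state)
  tables <- list()
  i <- 0L
  for (fraction in c("input", "IP")) {
    for (rep_k in seq_len(cfg$n_replicates)) {
      i <- i + 1L
      set.seed(cfg$seed + 100L + i)
      tables[[sprintf("%s_%d", fraction, rep_k)]] <-
        draw_contact_table(cfg, ref, weights, enriched, fraction, rep_k,
                           in_designated)
    }
  }
  gene_truth <- data.frame(
    gene_id = genes$gene_id, biotype = genes$biotype, chrom = genes$chrom,
    weight = weights, designated_mass = mass, enriched = enriched,
    enrichment_factor = ifelse(enriched, cfg$enrichment_factor, 1),
    stringsAsFactors = FALSE
  )
  list(tables = tables, gene_truth = gene_truth)
}

# Apply per-base substitutions at rate `rate` to a character vector of reads.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L), "")
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Turn simulated contacts into paired FASTQ reads with ground truth
#'
#' Read 1 is `[genomic DNA tag][bridge][template-switch G's][reverse-
#' complemented RNA fragment]`; read 2 is the reverse complement of read 1
#' (minimal mate simulation). With probability `noise` the bridge is
#' deleted; substitutions are applied at `sub_rate` per base. The truth
#' table records, per read, the fragments a correct parser emits: the DNA
#' tag as embedded and the RNA part after the same capped leading-G trim
#' the parser applies (when `bridge_cfg$gggg_trim` is on).
#'
#' @param contacts A contact data.frame from [simulate_contacts()].
#' @param ref Reference with genome sequences.
#' @param bridge_cfg A [bridge_config()].
#' @param cfg The [sim_config()] that produced the contacts.
#' @param seed RNG seed for the read-level randomness.
#' @return List with `reads` (`id, seq1, qual1, seq2, qual2`) and `truth`
#'   (per read: gene, coordinates, expected `dna_seq`/`rna_seq`, bridge
#'   deletion flag, number of added G's).
#' @export
contacts_to_reads <- function(contacts, ref, bridge_cfg, cfg,
                              seed = cfg$seed + 5L) {
  if (is.null(ref$genome)) stop("reference has no sequences")
  set.seed(seed)
  n <- nrow(contacts)
  chrom_str <- lapply(as.character(names(ref$genome)), function(cn)
    as.character(ref$genome[[cn]]))
  names(chrom_str) <- names(ref$genome)
  sub_chr <- function(chrom, s0, e0) {
    out <- character(length(chrom))
    for (cn in unique(chrom)) {
      sel <- chrom == cn
      out[sel] <- substring(chrom_str[[cn]], s0[sel] + 1L, e0[sel])
    }
    out
  }
  tag_fwd <- sub_chr(contacts$dna_chrom, contacts$dna_start, contacts$dna_end)
  flip <- stats::runif(n) < 0.5
  tag <- tag_fwd
  tag[flip] <- revcomp(tag_fwd[flip])
  rna_fwd <- sub_chr(contacts$rna_chrom, contacts$rna_start, contacts$rna_end)
  rna_sense <- rna_fwd
  neg <- contacts$rna_strand == "-"
  rna_sense[neg] <- revcomp(rna_fwd[neg])
  cdna <- revcomp(rna_sense)
  g <- if (cfg$ts_gggg) sample(0:3, n, replace = TRUE) else integer(n)
  seg <- paste0(strrep("G", g), cdna)
  del <- stats::runif(n) < cfg$noise
  seq1 <- paste0(tag, ifelse(del, "", bridge_cfg$bridge_seq), seg)
  seq1 <- apply_substitutions(seq1, cfg$sub_rate)
  seq2 <- revcomp(seq1)
  rna_expected <- if (isTRUE(bridge_cfg$gggg_trim))
    revcomp(sub("^G{1,4}", "", seg)) else revcomp(seg)
  reads <- data.frame(id = contacts$read_id, seq1 = seq1,
                      qual1 = strrep("I", nchar(seq1)), seq2 = seq2,
                      qual2 = strrep("I", nchar(seq2)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = contacts$read_id, gene_id = contacts$gene_id,
    rna_chrom = contacts$rna_chrom, rna_start = contacts$rna_start,
    rna_end = contacts$rna_end, dna_chrom = contacts$dna_chrom,
    dna_start = contacts$dna_start, dna_end = contacts$dna_end,
    fraction = contacts$fraction, replicate = contacts$replicate,
    dna_seq = tag, rna_seq = rna_expected,
    bridge_deleted = del, n_ts_g = g,
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}

#' Write a simulated reference to disk
#'
#' Writes `ref.fa` (when sequences exist), `genes.gtf`, `states.bed` and
#' `peaks.bed` into `dir`.
#'
#' @param ref A `redchip_reference`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  if (!is.null(ref$genome)) {
    fa <- file.path(dir, "ref.fa")
    Biostrings::writeXStringSet(ref$genome, fa)
    paths <- c(fasta = fa)
  }
  gtf <- file.path(dir, "genes.gtf")
  write_gtf_genes(ref$genes, gtf)
  st <- file.path(dir, "states.bed")
  write_bed(ref$states, st)
  pk <- file.path(dir, "peaks.bed")
  write_bed(ref$peaks, pk)
  c(paths, genes = gtf, states = st, peaks = pk)
}
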