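# Shared fixtures: everything is built in code at test time.

options(redchip.verbose = FALSE)

test_bridge <- function(...) bridge_config(example_bridge(), ...)

# Small read-scale simulation config: 2 x 200 kb genome, short genes.
tiny_sim_config <- function(seed = 1L, n_contacts = 500L, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 200000L,
             n_genes = 40L, gene_length_range = c(500L, 2000L),
             state_block_bp = 25000L, n_peaks = 10L,
             n_contacts_per_fraction = as.integer(n_contacts),
             cis_decay_scale = 5000, ...)
}

# Flatness check for a binned profile of n Bernoulli(p) placements: every
# bin inside the simultaneous (Bonferroni-corrected over bins) band at the
# nominal 3-sigma level, and a chi-square goodness-of-fit not rejecting
# flatness.
expect_flat_profile <- function(counts, n, p) {
  z <- (counts - n * p) / sqrt(n * p * (1 - p))
  alpha <- 2 * stats::pnorm(-3)                 # per-bin 3-sigma level
  z_star <- stats::qnorm(1 - alpha / (2 * length(counts)))
  expect_true(all(abs(z) <= z_star))
  p_chisq <- stats::pchisq(sum(z^2), df = length(counts), lower.tail = FALSE)
  expect_gt(p_chisq, 0.01)
}

# Brute-force Hamming-scan oracle for bridge matching (N = mismatch).
hamming_find <- function(seq, bridge, max_mismatches) {
  n <- nchar(seq)
  L <- nchar(bridge)
  if (L > n) return(integer(0))
  sv <- strsplit(seq, "")[[1]]
  bv <- strsplit(bridge, "")[[1]]
  hits <- integer(0)
  for (p in 0:(n - L)) {
    window <- sv[(p + 1):(p + L)]
    d <- sum(window != bv | window == "N")
    if (d <= max_mismatches) hits <- c(hits, p)
  }
  hits
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random valid contact table for round-trip and property tests.
random_contacts <- function(n, chroms = c("chrA", "chrB"), len = 100000L) {
  rs <- sample.int(len - 200L, n, replace = TRUE)
  ds <- sample.int(len - 200L, n, replace = TRUE)
  data.frame(
    read_id = sprintf("rd%05d", seq_len(n)),
    rna_chrom = sample(chroms, n, replace = TRUE),
    rna_start = rs, rna_end = rs + sample(20:80, n, replace = TRUE),
    rna_strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = sample(c("G1", "G2", "unassigned"), n, replace = TRUE),
    dna_chrom = sample(chroms, n, replace = TRUE),
    dna_start = ds, dna_end = ds + 20L,
    fraction = sample(c("IP", "input"), n, replace = TRUE),
    replicate = sample(1:2, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

write_fastq_file <- function(ids, seqs, path, suffix = "") {
  writeLines(paste0("@", ids, suffix, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
}
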