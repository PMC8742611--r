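make_toy_genome <- function(seed = 21, len = 600) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(chrA = random_dna(len), chrB = random_dna(len)))
}

test_that("the exact-match aligner reports strand, coordinates and uniqueness", {
  genome <- make_toy_genome()
  chrA <- as.character(genome[["chrA"]])
  fwd <- substr(chrA, 101, 124)                    # unique forward 24-mer
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrA, 201, 224))))  # hits the minus strand
  parts <- data.frame(
    read_id = c("r1", "r2", "r3"),
    part = c("dna", "rna", "rna"),
    seq = c(fwd, rev, strrep("ACGT", 6)),
    stringsAsFactors = FALSE
  )
  al <- align_exact(parts, genome)
  r1 <- al[al$read_id == "r1", ]
  expect_equal(r1$chrom, "chrA")
  expect_equal(r1$start, 100L)
  expect_equal(r1$end, 124L)
  expect_equal(r1$strand, "+")
  expect_true(r1$unique)
  r2 <- al[al$read_id == "r2", ]
  expect_equal(r2$start, 200L)
  expect_equal(r2$strand, "-")
  expect_true(r2$unique)
  # "ACGTACGT..." occurs nowhere in this random toy genome
  expect_false("r3" %in% al$read_id)
})

test_that("a part occurring on two chromosomes is flagged non-unique", {
  set.seed(22)
  shared <- random_dna(24)
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste0(random_dna(100), shared, random_dna(100)),
    chrB = paste0(random_dna(50), shared, random_dna(150))
  ))
  al <- align_exact(data.frame(read_id = "r", part = "dna", seq = shared,
                               stringsAsFactors = FALSE), genome)
  expect_equal(nrow(al), 1L)
  expect_false(al$unique)
})

test_that("SAM ingestion keeps coordinates only and applies uniqueness rules", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq20 <- strrep("AC", 10)
  writeLines(c(
    "@SQ\tSN:chrA\tLN:1000",
    paste("u1", 0, "chrA", 101, 60, "20M", "*", 0, 0, seq20, strrep("I", 20),
          sep = "\t"),
    paste("u2", 16, "chrA", 201, 0, "20M", "*", 0, 0, seq20, strrep("I", 20),
          sep = "\t"),
    paste("u3", 4, "*", 0, 0, "*", "*", 0, 0, seq20, strrep("I", 20),
          sep = "\t"),
    paste("u4", 256, "chrA", 301, 60, "20M", "*", 0, 0, seq20,
          strrep("I", 20), sep = "\t")
  ), sam)
  al <- ingest_alignments(sam, "dna")
  expect_equal(al$read_id, c("u1", "u2", "u4"))  # unmapped skipped
  expect_equal(al$start[1], 100L)
  expect_equal(al$end[1], 120L)
  expect_equal(al$strand, c("+", "-", "+"))
  expect_equal(al$unique, c(TRUE, FALSE, FALSE))  # mapq 0 and secondary
  expect_error(ingest_alignments(sam, "dna", chroms = "chrB"),
               "unknown reference")
})

test_that("TSV alignment ingestion round-trips the six columns", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  x <- data.frame(read_id = c("a", "b"), chrom = "chrA",
                  start = c(10L, 50L), end = c(30L, 70L),
                  strand = c("+", "-"), unique = c(TRUE, FALSE),
                  stringsAsFactors = FALSE)
  utils::write.table(x, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  al <- ingest_alignments(tsv, "rna")
  expect_equal(al[, names(x)], x)
  expect_equal(unique(al$part), "rna")
})

test_that("gene assignment is strand-aware with deterministic tie-breaks", {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gBig", "gSmall", "gMinus"),
    chrom = "chrA",
    start = c(100L, 130L, 500L, 510L, 850L),
    end = c(130L, 200L, 800L, 540L, 950L),
    strand = c("+", "+", "+", "+", "-"),
    biotype = "protein_coding",
    stringsAsFactors = FALSE
  )
  aln <- data.frame(
    chrom = "chrA",
    start = c(100L, 110L, 510L, 860L, 960L),
    end = c(140L, 120L, 540L, 900L, 990L),
    strand = c("+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE
  )
  got <- assign_gene(aln, genes)
  # overlaps gA by 30 and gB by 10 -> larger overlap wins
  expect_equal(got[1], "gA")
  expect_equal(got[2], "gA")
  # equal 30 bp overlap with gBig and gSmall -> smaller gene wins
  expect_equal(got[3], "gSmall")
  # only a minus-strand gene overlaps a plus alignment -> unassigned
  expect_equal(got[4], "unassigned")
  expect_equal(got[5], "unassigned")
})

test_that("contact building pairs unique parts, deduplicates and conserves reads", {
  genes <- data.frame(gene_id = "gX", chrom = "chrA", start = 90L,
                      end = 200L, strand = "+", biotype = "lincRNA",
                      stringsAsFactors = FALSE)
  aln <- function(id, part, chrom, start, end, strand = "+", unique = TRUE)
    data.frame(read_id = id, part = part, chrom = chrom, start = start,
               end = end, strand = strand, unique = unique,
               stringsAsFactors = FALSE)
  alns <- rbind(
    aln("r1", "rna", "chrA", 100L, 130L), aln("r1", "dna", "chrB", 50L, 70L),
    aln("r2", "rna", "chrA", 100L, 130L), aln("r2", "dna", "chrB", 50L, 70L),
    aln("r3", "rna", "chrA", 140L, 170L),
    aln("r3", "dna", "chrB", 80L, 100L, unique = FALSE),
    aln("r4", "dna", "chrB", 10L, 30L)   # rna part unmapped
  )
  ct <- build_contacts(alns, alns, genes, "IP", 1,
                       read_ids = c("r1", "r2", "r3", "r4"))
  expect_equal(nrow(ct), 1L)             # r2 is a PCR duplicate of r1
  expect_equal(ct$gene_id, "gX")
  st <- attr(ct, "stats")
  expect_equal(unname(st[c("n_reads", "n_both_unique", "n_duplicate",
                           "n_contacts")]), c(4L, 2L, 1L, 1L))
  # conservation: OK reads in = contacts + rejected
  expect_equal(st[["n_reads"]],
               st[["n_contacts"]] + (st[["n_reads"]] - st[["n_both_unique"]]) +
                 st[["n_duplicate"]])
})

test_that("per-gene counts conserve the table total", {
  ct <- random_contacts(50)
  cc <- gene_contact_counts(ct)
  expect_equal(sum(cc) + sum(ct$gene_id == "unassigned"), nrow(ct))
  expect_equal(length(gene_contact_counts(ct[0, ])), 0L)
})

test_that("simulated contacts survive the full read round-trip almost losslessly", {
  cfg <- tiny_sim_config(seed = 13, n_contacts = 1200)
  ref <- simulate_reference(cfg)
  sim <- simulate_contacts(cfg, ref)
  truth <- sim$tables$input_1
  rr <- contacts_to_reads(truth, ref, test_bridge(), cfg)
  dec <- deconvolve_library(rr$reads, cfg = test_bridge())
  al <- align_exact(ok_parts(dec$reads), ref$genome)
  ct <- build_contacts(al, al, ref$genes, "input", 1,
                       read_ids = dec$reads$read_id[dec$reads$status == "OK"])
  key_truth <- paste(truth$gene_id, truth$dna_chrom, truth$dna_start)
  key_out <- paste(ct$gene_id, ct$dna_chrom, ct$dna_start)
  expect_gte(mean(key_truth %in% key_out), 0.99)
  # conservation through the stage
  st <- attr(ct, "stats")
  expect_equal(st[["n_both_unique"]],
               st[["n_contacts"]] + st[["n_duplicate"]])
})
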