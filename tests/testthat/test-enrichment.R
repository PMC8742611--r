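test_that("cis windows clamp to the chromosome", {
  g <- list(start = 2000000L, end = 2050000L)
  expect_equal(unname(cis_window(g, 1e6, 1e7)), c(1e6, 3050000))
  expect_equal(unname(cis_window(list(start = 0L, end = 1000L), 1e6, 1e7)),
               c(0, 1001000))
  expect_equal(unname(cis_window(g, 0, 1e7)), c(2000000, 2050000))
})

test_that("cis/trans counting follows the window and chromosome rules", {
  gene <- list(gene_id = "g", chrom = "chr1", start = 4.0e6, end = 4.1e6)
  ct <- random_contacts(10, chroms = "chr1")
  ct$gene_id <- "g"
  ct$dna_chrom <- c(rep("chr1", 7), rep("chr2", 3))
  ct$dna_start <- c(rep(4.05e6, 3), 3.5e6, 4.6e6,   # inside the 1 Mb window
                    9.2e6, 9.5e6,                   # parent, > 1 Mb away
                    1e6, 2e6, 3e6)
  ct$dna_end <- ct$dna_start + 20
  expect_equal(unname(count_cis_trans(gene, ct, window_bp = 1e6)), c(5L, 3L))
  expect_equal(unname(count_cis_trans(gene, ct[0, ], 1e6)), c(0L, 0L))
  # all contacts inside the gene body count as cis even at window 0
  body <- ct[1:3, ]
  expect_equal(unname(count_cis_trans(gene, body, window_bp = 0))[1], 3L)
})

test_that("fold change matches the worked example and the count filter", {
  expect_identical(fold_change(30, 1000, 20, 1000), 1.5)
  expect_identical(fold_change(20, 1000, 20, 1000), 1)
  expect_true(is.na(fold_change(30, 1000, 5, 1000)))
  expect_error(fold_change(3, 0, 2, 10), "totals")
})

test_that("fold change is invariant under library rescaling", {
  set.seed(31)
  for (i in 1:20) {
    ci <- sample(10:500, 1); ti <- sample(1000:5000, 1)
    cn <- sample(10:500, 1); tn <- sample(1000:5000, 1)
    base <- fold_change(ci, ti, cn, tn)
    for (c_scale in c(2, 10, 0.5)) {
      scaled <- fold_change(ci * c_scale, ti * c_scale, cn, tn,
                            min_count = 5)
      expect_equal(scaled, base)
    }
  }
})

test_that("the enriched call is strict, replicate-wide and monotone", {
  expect_true(call_enriched(c(1.4, 1.35), 1.3))
  expect_false(call_enriched(c(1.4, 1.2), 1.3))
  expect_false(call_enriched(c(1.3, 1.5), 1.3))  # strictly greater
  expect_false(call_enriched(c(NA, 2.0), 1.3))
  set.seed(32)
  for (i in 1:20) {
    fc <- runif(2, 0.5, 3)
    calls <- vapply(c(1, 1.3, 2, 3), function(th) call_enriched(fc, th), TRUE)
    expect_true(all(diff(calls) <= 0))
  }
})

seg4 <- data.frame(chrom = "chrA",
                   start = c(0L, 100L, 200L, 300L),
                   end = c(100L, 200L, 300L, 400L),
                   label = c("S", "T", "U", "V"),
                   stringsAsFactors = FALSE)

state_ct <- function(mids, chrom = "chrA") {
  ct <- random_contacts(length(mids), chroms = chrom)
  ct$dna_chrom <- chrom
  ct$dna_start <- as.integer(mids - 5L)
  ct$dna_end <- as.integer(mids + 5L)
  ct
}

test_that("state percentages sum to 100 over classified contacts", {
  all_s <- state_percentages(state_ct(rep(50, 10)), seg4)
  expect_equal(all_s$percent[all_s$state == "S"], 100)
  expect_equal(sum(all_s$count), 10L)

  half <- state_percentages(state_ct(c(rep(50, 5), rep(150, 5))), seg4)
  expect_equal(half$percent[half$state %in% c("S", "T")], c(50, 50))

  # a midpoint beyond every segment is excluded from the denominator
  mixed <- state_percentages(state_ct(c(rep(50, 4), 900)), seg4)
  expect_equal(attr(mixed, "n_unclassified"), 1L)
  expect_equal(sum(mixed$percent), 100)
})

test_that("state ratios are depth-normalized IP/input proportions", {
  ip <- state_ct(rep(50, 40))                      # all in S
  input <- state_ct(rep(c(50, 150, 250, 350), each = 10))  # uniform
  r <- state_ratio_ip_input(ip, input, seg4)
  expect_equal(r$ratio[r$state == "S"], 4)         # (40/40)/(10/40)
  expect_equal(r$ratio[r$state == "T"], 0)

  same <- state_ratio_ip_input(input, input, seg4)
  expect_equal(same$ratio, rep(1, 4))

  # a state with no input contacts has an undefined ratio
  r2 <- state_ratio_ip_input(ip, state_ct(rep(150, 10)), seg4)
  expect_true(is.na(r2$ratio[r2$state == "S"]))
})

test_that("metaprofile puts center-placed DNA parts in the center bin", {
  peaks <- data.frame(chrom = "chrA", start = c(900L, 4900L),
                      end = c(1100L, 5100L), label = "",
                      stringsAsFactors = FALSE)
  ct <- state_ct(c(rep(1000, 6), rep(5000, 4), 40000))
  mp <- peak_metaprofile(ct, peaks, flank_bp = 10000, n_bins = 41)
  expect_equal(nrow(mp), 41L)
  expect_equal(mp$count[21], 10L)             # center bin
  expect_equal(sum(mp$count), 10L)            # the far contact is excluded
  expect_equal(mp$cpm[21], 1e6 * 10 / 11)
  expect_error(peak_metaprofile(ct, peaks[0, ]), "empty peak")
  expect_error(peak_metaprofile(ct, peaks, n_bins = 40), "odd")
})

test_that("metaprofile is flat for uniform contacts around gridded peaks", {
  set.seed(33)
  n <- 40000L
  len <- 1e6
  centers <- seq(12500, by = 25000, length.out = 40)
  peaks <- data.frame(chrom = "chrU", start = centers - 100,
                      end = centers + 100, label = "",
                      stringsAsFactors = FALSE)
  pos <- sample.int(len - 20L, n, replace = TRUE)
  ct <- random_contacts(n, chroms = "chrU")
  ct$dna_chrom <- "chrU"; ct$dna_start <- pos; ct$dna_end <- pos + 20L
  mp <- peak_metaprofile(ct, peaks, flank_bp = 10000, n_bins = 41)
  p <- (20000 / 41) * length(centers) / len
  expect_flat_profile(mp$count, n, p)
})

test_that("rank-sum test reproduces the exact two-sided enumeration p", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)                 # 2 * 1/20
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 5))$p_value, 1)
  expect_error(rank_sum_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("exact path agrees with wilcox.test on tie-free samples", {
  set.seed(34)
  for (i in 1:30) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    x <- sample(seq_len(50), na); y <- sample(seq_len(50) + 100, nb)
    if (runif(1) < 0.5) y <- y - 100 + 0.5   # interleave, still tie-free
    r <- rank_sum_test(x, y)
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
    expect_equal(r$statistic, unname(w$statistic))
  }
})

test_that("exact path handles ties through midrank enumeration", {
  # independent oracle: enumerate every assignment from scratch
  oracle <- function(x, y) {
    v <- c(x, y); na <- length(x)
    r <- rank(v)
    obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    cols <- utils::combn(length(v), na)
    us <- apply(cols, 2, function(i) sum(r[i])) - na * (na + 1) / 2
    min(1, 2 * min(mean(us <= obs + 1e-9), mean(us >= obs - 1e-9)))
  }
  set.seed(35)
  for (i in 1:15) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- sample(1:4, na, replace = TRUE)
    y <- sample(2:6, nb, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, oracle(x, y))
  }
})

test_that("large-sample path matches a Monte-Carlo permutation oracle", {
  set.seed(36)
  x <- round(rnorm(18, 0, 1), 1)
  y <- round(rnorm(25, 0.6, 1), 1)
  r <- rank_sum_test(x, y)
  v <- c(x, y); na <- length(x)
  rk <- rank(v)
  obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(y) / 2
  B <- 10000
  us <- replicate(B, {
    i <- sample(length(v), na)
    sum(rk[i]) - na * (na + 1) / 2
  })
  p_mc <- min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(r$p_value - p_mc), 4 * se + 0.01)
})

test_that("biotype comparison pulls defined fold changes from a results table", {
  res <- data.frame(
    biotype = rep(c("antisense", "lincRNA"), each = 5),
    fc_rep1 = c(2.0, 2.2, 1.9, 2.5, NA, 1.0, 1.1, 0.9, 1.2, 1.05),
    fc_rep2 = c(2.1, 2.0, 2.0, 2.4, 1.8, 1.0, 1.0, 1.0, 1.1, 0.95),
    stringsAsFactors = FALSE
  )
  out <- biotype_fc_test(res, "antisense", "lincRNA")
  expect_equal(out$n_a, 4L)    # the NA gene is dropped
  expect_equal(out$n_b, 5L)
  expect_lt(out$p_value, 0.05)
})

test_that("pairwise biotype comparisons report BH-adjusted p values", {
  set.seed(38)
  res <- data.frame(
    biotype = rep(c("antisense", "lincRNA", "protein_coding"), each = 8),
    fc_rep1 = c(rnorm(8, 2, 0.2), rnorm(8, 1, 0.1), rnorm(8, 1, 0.1)),
    fc_rep2 = c(rnorm(8, 2, 0.2), rnorm(8, 1, 0.1), rnorm(8, 1, 0.1)),
    stringsAsFactors = FALSE
  )
  out <- biotype_fc_tests(res)
  expect_equal(nrow(out), 3L)
  expect_equal(out$p_adjusted, stats::p.adjust(out$p_value, "BH"))
  ab <- out[out$biotype_a == "antisense" & out$biotype_b == "lincRNA", ]
  expect_equal(ab$p_value,
               biotype_fc_test(res, "antisense", "lincRNA")$p_value)
})

test_that("overlap test equals the hypergeometric tail sum", {
  tail_sum <- function(k, sa, sb, N) {
    j <- k:min(sa, sb)
    sum(choose(sb, j) * choose(N - sb, sa - j)) / choose(N, sa)
  }
  # the published-scale configuration: 18 of 22 hits against a 100-gene list
  a <- sprintf("a%02d", 1:22)
  b <- c(a[1:18], sprintf("b%02d", 1:82))
  r <- overlap_test(a, b, 1000)
  expect_equal(r$overlap, 18L)
  expect_equal(r$p_value, tail_sum(18, 22, 100, 1000), tolerance = 1e-12)

  set.seed(37)
  for (i in 1:40) {
    N <- sample(50:500, 1)
    u <- sprintf("g%04d", seq_len(N))
    sa <- sample(u, sample(5:30, 1))
    sb <- sample(u, sample(5:60, 1))
    r <- overlap_test(sa, sb, N)
    expect_equal(r$p_value,
                 tail_sum(r$overlap, length(sa), length(sb), N),
                 tolerance = 1e-12)
  }
  expect_equal(overlap_test(letters[1:5], letters[10:15], 100)$overlap, 0L)
  expect_equal(overlap_test(letters[1:5], letters, 26)$p_value, 1)
  expect_error(overlap_test(letters[1:5], letters, 20), "universe")
})

test_that("RNA ranking orders by count with lexicographic ties", {
  r <- rank_rnas(c(B = 30, A = 50, C = 20))
  expect_equal(r$gene_id, c("A", "B", "C"))
  expect_equal(r$share, c(0.5, 0.3, 0.2))
  expect_equal(rank_rnas(c(X = 7))$share, 1)
  tie <- rank_rnas(c(Zz = 5, Aa = 5))
  expect_equal(tie$gene_id, c("Aa", "Zz"))
  expect_equal(nrow(rank_rnas(integer(0))), 0L)
})
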