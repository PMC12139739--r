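test_that("only primary records pass the scan", {
  bam <- write_test_bam(c(
    sam_line("r1", "tx1", 1, 100, flag = 0L, tags = "CB:Z:BC1"),
    sam_line("r2", "tx1", 10, 80, flag = 256L),
    sam_line("r3", "tx1", 20, 60, flag = 2048L)
  ))
  reads <- scan_bam(bam)
  expect_equal(nrow(reads), 1L)
  expect_equal(reads$qname, "r1")
})

test_that("the mean-quality filter is strict: reads at exactly the threshold fail", {
  bam <- write_test_bam(c(
    sam_line("q7", "tx1", 1, 50, qscore = 7L),
    sam_line("q8", "tx1", 1, 50, qscore = 8L)
  ))
  reads <- scan_bam(bam, min_qscore = 7)
  expect_equal(reads$qname, "q8")
})

test_that("sentinel tag values count as absent", {
  bam <- write_test_bam(c(
    sam_line("r1", "tx1", 1, 50, tags = c("CB:Z:BC1", "GN:Z:-")),
    sam_line("r2", "tx1", 1, 50, tags = c("CB:Z:BC1", "GN:Z:G1"))
  ))
  reads <- scan_bam(bam)
  expect_identical(reads$gene, c(NA, "G1"))
})

test_that("length summary matches direct arithmetic and degenerate cases", {
  bam <- write_test_bam(c(
    sam_line("a", "tx1", 1, 100, tags = "CB:Z:B"),
    sam_line("b", "tx1", 1, 100, tags = "CB:Z:B"),
    sam_line("c", "tx1", 1, 300, tags = "CB:Z:B")
  ))
  s <- read_length_summary(scan_bam(bam))
  all_p <- s[s$class == "all_primary", ]
  expect_equal(all_p$mean_bp, mean(c(100, 100, 300)), tolerance = 1e-12)
  expect_equal(all_p$median_bp, 100)
  # modal 50-bp bin contains 100: [100, 150), midpoint 125
  expect_equal(all_p$mode_bp, 125)
  # empty classes: no gene/transcript tags anywhere
  expect_equal(s$n[s$class == "gene_tagged"], 0L)
  expect_true(is.na(s$mean_bp[s$class == "gene_tagged"]))

  # all reads the same length: mean = median, mode midpoint of that bin
  bam2 <- write_test_bam(sapply(1:5, function(i) sam_line(paste0("r", i), "tx1", 1, 220)))
  s2 <- read_length_summary(scan_bam(bam2))
  expect_equal(s2$mean_bp[1], 220)
  expect_equal(s2$median_bp[1], 220)
  expect_equal(s2$mode_bp[1], 225)
})

test_that("identification rates: forced and binomial-recovery cases", {
  tx <- toy_txome()
  # no tags at all
  bam0 <- write_test_bam(c(sam_line("r1", "tx1", 1, 50), sam_line("r2", "tx1", 1, 60)))
  r0 <- identification_rates(scan_bam(bam0))
  expect_equal(c(r0$frac_gene_identified, r0$frac_transcript_identified, r0$frac_neither),
               c(0, 0, 1))
  # every read fully tagged
  prof1 <- library_profile(gene_tag_rate = 1, transcript_tag_rate = 1, seed = 2)
  r1 <- identification_rates(scan_bam(simulate_reads(tx, prof1, 300)$bam))
  expect_equal(c(r1$frac_gene_identified, r1$frac_transcript_identified, r1$frac_neither),
               c(1, 1, 0))
  # partition sums to 1
  prof <- library_profile(gene_tag_rate = 0.6, transcript_tag_rate = 0.45, seed = 8)
  n <- 20000
  rr <- identification_rates(scan_bam(simulate_reads(tx, prof, n)$bam))
  expect_equal(rr$frac_gene_only + rr$frac_transcript_identified + rr$frac_neither, 1,
               tolerance = 1e-9)
  expect_lt(abs(rr$frac_gene_identified - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  expect_lt(abs(rr$frac_transcript_identified - 0.45), 3 * sqrt(0.45 * 0.55 / n))
  expect_lte(rr$frac_transcript_identified, rr$frac_gene_identified)
  expect_error(identification_rates(empty_read_table()), "empty")
})

test_that("gene read fraction handles target sets and denominators", {
  tx <- toy_txome()
  prof <- library_profile(gene_tag_rate = 1, transcript_tag_rate = 1,
                          dominant_gene_id = "GA", dominant_gene_fraction = 0.25,
                          seed = 5)
  n <- 10000
  reads <- scan_bam(simulate_reads(tx, prof, n)$bam)
  gf <- gene_read_fraction(reads, "GA")
  expect_lt(abs(gf$fraction - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # absent target -> 0; all genes at full tag rate -> 1
  expect_equal(gene_read_fraction(reads, "ABSENT")$fraction, 0)
  expect_equal(gene_read_fraction(reads, c("GA", "GB"))$fraction, 1)
  expect_error(gene_read_fraction(reads, character(0)), "non-empty")
})

test_that("depletion efficiency and off-target shifts behave as constructed", {
  tx <- toy_txome()
  prof <- library_profile(gene_tag_rate = 1, transcript_tag_rate = 1,
                          dominant_gene_id = "GA", dominant_gene_fraction = 0.25,
                          seed = 12)
  pre <- scan_bam(simulate_reads(tx, prof, 8000)$bam)
  # identical streams: zero efficiency, zero off-target shift
  same <- depletion_report(pre, pre, "GA")
  expect_equal(same$efficiency, 0)
  expect_true(all(abs(same$off_target$delta) < 1e-12))
  # remove 95% of target reads; expected efficiency from the construction
  is_t <- !is.na(pre$gene) & pre$gene == "GA"
  drop <- withr::with_seed(1, which(is_t & stats::runif(nrow(pre)) < 0.95))
  post <- pre[-drop, ]
  rep95 <- depletion_report(pre, post, "GA")
  T0 <- sum(is_t); k <- length(drop); N <- nrow(pre)
  eff_expected <- 1 - ((T0 - k) / (N - k)) / (T0 / N)
  expect_equal(rep95$efficiency, eff_expected, tolerance = 1e-12)
  expect_gt(rep95$efficiency, 0.9)
  # target fully absent post
  full <- depletion_report(pre, pre[!is_t, ], "GA")
  expect_equal(full$efficiency, 1)
  # pre fraction 0 -> undefined
  expect_message(und <- depletion_report(pre[!is_t, ], pre[!is_t, ], "GA"), "undefined")
  expect_true(is.na(und$efficiency))
})

test_that("summaries are invariant to read order", {
  tx <- toy_txome()
  prof <- library_profile(gene_tag_rate = 0.7, transcript_tag_rate = 0.5, seed = 31)
  reads <- scan_bam(simulate_reads(tx, prof, 1000)$bam)
  shuf <- reads[withr::with_seed(2, sample(nrow(reads))), ]
  expect_equal(read_length_summary(shuf), read_length_summary(reads))
  expect_equal(identification_rates(shuf), identification_rates(reads))
  expect_equal(gene_read_fraction(shuf, "GA")$fraction,
               gene_read_fraction(reads, "GA")$fraction)
})

test_that("libraries with longer truncation means test as stochastically longer", {
  tx <- generate_transcriptome(5, c(1, 2), c(4, 7), exon_len = c(200, 400), seed = 17)
  p600 <- library_profile("five_prime", truncation_mean_bp = 600,
                          truncation_sd_bp = 150, seed = 41)
  p900 <- library_profile("five_prime", truncation_mean_bp = 900,
                          truncation_sd_bp = 150, seed = 42)
  a <- simulate_reads(tx, p600, 5000, write_bam = FALSE)$truth$length
  b <- simulate_reads(tx, p900, 5000, write_bam = FALSE)$truth$length
  ht <- compare_read_lengths(a, b, alternative = "second_longer")
  expect_lt(ht$p.value, 0.05)
  # and the reversed alternative is not significant
  expect_gt(compare_read_lengths(a, b, alternative = "first_longer")$p.value, 0.5)
})
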