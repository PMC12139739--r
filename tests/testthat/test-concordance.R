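sim_for_concordance <- function(seed = 1, n_cells = 120) {
  tx <- generate_transcriptome(10, c(1, 3), c(2, 4), seed = 30)
  simulate_count_matrices(tx, n_cells = n_cells, n_clusters = 3,
                          replicates = c("r1", "r2"), seed = seed)
}

test_that("pseudobulk reduces to rows or column sums in the degenerate groupings", {
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  # one cell per group
  per_cell <- pseudobulk(m, stats::setNames(paste0("c", 1:4), paste0("c", 1:4)))
  expect_equal(unname(per_cell[, paste0("c", 1:4)]), unname(m))
  # all cells one group
  one <- pseudobulk(m, stats::setNames(rep("all", 4), paste0("c", 1:4)))
  expect_equal(unname(one[, 1]), unname(rowSums(m)))
})

test_that("pseudobulk equals a double-loop oracle and conserves counts", {
  withr::with_seed(40, {
    counts <- matrix(stats::rpois(200 * 50, 2), 50, 200,
                     dimnames = list(sprintf("f%02d", 1:50), sprintf("c%03d", 1:200)))
    ct <- stats::setNames(sample(paste0("T", 1:3), 200, TRUE), colnames(counts))
    rp <- stats::setNames(sample(c("r1", "r2"), 200, TRUE), colnames(counts))
    pb <- pseudobulk(counts, ct, rp)
    expect_equal(unname(pb),
                 unname(naive_pseudobulk(counts,
                                         stats::setNames(paste(ct, rp, sep = ":"),
                                                         names(ct)))),
                 ignore_attr = TRUE)
    expect_equal(sum(pb), sum(counts))
    # sparse input gives the same result
    pbs <- pseudobulk(Matrix::Matrix(counts, sparse = TRUE), ct, rp)
    expect_equal(pb, pbs, ignore_attr = TRUE)
  })
})

test_that("pseudobulk excludes unlabelled cells with a warning", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("c1", "c2", "c3")))
  expect_warning(pb <- pseudobulk(m, c(c1 = "x", c2 = "x")), "lack")
  expect_equal(sum(pb), sum(m[, 1:2]))
})

test_that("usage fractions form a simplex per (group, gene) and flag absences", {
  sim <- sim_for_concordance()
  pb <- pseudobulk(sim$tx, labels_of(sim$cells, "cluster"),
                   labels_of(sim$cells, "replicate"))
  tx <- generate_transcriptome(10, c(1, 3), c(2, 4), seed = 30)
  uf <- usage_fractions(pb, tx2gene(tx))
  sums <- uf %>% dplyr::group_by(group, gene_id) %>%
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # single-transcript genes always have fraction 1 where expressed
  singles <- names(which(table(tx2gene(tx)) == 1))
  one_tx <- uf[uf$gene_id %in% singles, ]
  expect_true(all(one_tx$fraction == 1))
  # a zero-count gene in one group is absent, not zero-divided
  pb0 <- pb
  g0 <- tx2gene(tx)[rownames(pb0)] == "GENE001"
  pb0[g0, 1] <- 0
  uf0 <- usage_fractions(pb0, tx2gene(tx))
  expect_false(any(uf0$group == colnames(pb0)[1] & uf0$gene_id == "GENE001"))
  expect_true(nrow(attr(uf0, "absent")) >= 1)
  # unmapped transcript errors by name
  expect_error(usage_fractions(pb, tx2gene(tx)[-1]), "without a gene mapping")
  # invariant to uniform scaling of a group's counts
  pb2 <- pb; pb2[, 2] <- pb2[, 2] * 7
  uf2 <- usage_fractions(pb2, tx2gene(tx))
  expect_equal(uf2$fraction, uf$fraction, tolerance = 1e-12)
})

test_that("confusion matrices match a pairwise oracle and track exclusives", {
  withr::with_seed(50, {
    bcs <- sprintf("b%03d", 1:500)
    la <- stats::setNames(sample(paste0("A", 1:4), 500, TRUE), bcs)
    lb <- stats::setNames(sample(paste0("B", 1:3), 500, TRUE), bcs)
    cm <- confusion_matrix(la, lb)
    expect_equal(unclass(cm), naive_confusion(la, lb), ignore_attr = TRUE)
    expect_equal(sum(cm), 500)
    expect_true(all(abs(rowSums(row_normalize(cm)) - 1) < 1e-12))
    # identical labelings give a diagonal matrix
    cd <- confusion_matrix(la, la)
    expect_true(all(cd[upper.tri(cd) | lower.tri(cd)] == 0))
    # exclusive barcodes are reported, grand total covers the intersection
    cm2 <- confusion_matrix(la[1:400], lb[201:500])
    expect_equal(sum(cm2), 200)
    expect_equal(attr(cm2, "only_a"), 200)
    expect_equal(attr(cm2, "only_b"), 100)
    expect_error(confusion_matrix(la[1:10], lb[11:20]), "no barcode shared")
  })
})

test_that("concordance is perfect for identical labelings and invariant to renaming", {
  withr::with_seed(60, {
    bcs <- sprintf("b%03d", 1:300)
    la <- stats::setNames(sample(paste0("A", 1:3), 300, TRUE), bcs)
    sc <- concordance_scores(confusion_matrix(la, la))
    expect_true(all(sc$concordance == 1))
    expect_equal(attr(sc, "overall"), 1)
    # permuted label names: still 100% after matching
    ren <- c(A1 = "Z9", A2 = "Z1", A3 = "Z5")
    sc2 <- concordance_scores(confusion_matrix(la, stats::setNames(ren[la], bcs)))
    expect_equal(attr(sc2, "overall"), 1)
    expect_true(all(sc2$concordance == 1))
  })
})

test_that("a split class scores 100%+100% under argmax but leaves one unmatched under hungarian", {
  bcs <- sprintf("b%02d", 1:60)
  la <- stats::setNames(rep(c("A1", "A2"), each = 30), bcs)
  lb <- la
  lb[1:15] <- "B1a"; lb[16:30] <- "B1b"; lb[31:60] <- "B2"
  cm <- confusion_matrix(la, lb)
  am <- concordance_scores(cm, "argmax")
  expect_equal(am$matched_a[am$class_b %in% c("B1a", "B1b")], c("A1", "A1"))
  expect_equal(am$concordance, c(1, 1, 1))
  expect_equal(attr(am, "overall"), 1)
  hu <- concordance_scores(cm, "hungarian")
  expect_equal(sum(is.na(hu$matched_a)), 1)
  expect_equal(attr(hu, "overall"), (30 + 15) / 60)
})

test_that("argmax ties resolve toward the larger then lexicographically first A class", {
  cm <- structure(matrix(c(5L, 5L, 0L,
                           0L, 2L, 0L), nrow = 3,
                         dimnames = list(c("A2", "A1", "A3"), c("B1", "B2"))),
                  class = c("confusion_matrix", "matrix", "array"))
  # B1 ties A2/A1 at 5; A1 has the larger row total (5+2=7) -> A1
  sc <- concordance_scores(cm)
  expect_equal(sc$matched_a[sc$class_b == "B1"], "A1")
  # equal row totals -> lexicographic
  cm2 <- structure(matrix(c(4L, 4L), nrow = 2,
                          dimnames = list(c("A2", "A1"), "B1")),
                   class = c("confusion_matrix", "matrix", "array"))
  expect_equal(concordance_scores(cm2)$matched_a, "A1")
})

test_that("10% label noise yields about 90% overall concordance", {
  withr::with_seed(70, {
    n <- 2000
    bcs <- sprintf("b%04d", seq_len(n))
    la <- stats::setNames(sample(paste0("A", 1:4), n, TRUE), bcs)
    lb <- la
    flip <- stats::runif(n) < 0.10
    lb[flip] <- vapply(la[flip], function(x) sample(setdiff(paste0("A", 1:4), x), 1),
                       character(1))
    ov <- attr(concordance_scores(confusion_matrix(la, lb)), "overall")
    expect_lt(abs(ov - 0.9), 3 * sqrt(0.9 * 0.1 / n))
  })
})
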