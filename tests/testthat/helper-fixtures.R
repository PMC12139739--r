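# Shared fixtures and independent naive oracles used across the suite.

# Small fixed annotation: two genes on opposite strands, shared and unique
# junctions, one single-exon transcript.
toy_txome <- function() {
  as_transcriptome(tibble::tribble(
    ~gene_id, ~transcript_id, ~chrom, ~strand, ~start, ~end,
    "GA", "GA.T1", "chr1", "+", 100L, 200L,
    "GA", "GA.T1", "chr1", "+", 300L, 400L,
    "GA", "GA.T1", "chr1", "+", 500L, 600L,
    "GA", "GA.T2", "chr1", "+", 100L, 200L,   # skips the middle exon
    "GA", "GA.T2", "chr1", "+", 500L, 600L,
    "GB", "GB.T1", "chr2", "-", 1000L, 1150L,
    "GB", "GB.T1", "chr2", "-", 1300L, 1400L,
    "GB", "GB.T2", "chr2", "-", 2000L, 2080L
  ))
}

# Write a BAM from raw SAM record fields (for hand-crafted flag/quality cases).
write_test_bam <- function(records, sq = c(tx1 = 1000L), path = tempfile(fileext = ".bam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, records), sam)
  on.exit(unlink(sam))
  Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                   indexDestination = TRUE)
}

# One SAM line; qscore is a constant phred value for all bases.
sam_line <- function(qname, rname, pos, len, flag = 0L, qscore = 20L,
                     tags = character(0)) {
  paste(c(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  qname, flag, rname, pos, len,
                  strrep("A", len), strrep(rawToChar(as.raw(qscore + 33L)), len)),
          tags), collapse = "\t")
}

# ---- independent oracles (plain loops; no sclrqc logic reused) ------------

# Tag-class counts straight from the BAM bytes.
naive_class_counts <- function(bam, whitelist, min_q = 7) {
  p <- Rsamtools::ScanBamParam(what = c("flag", "qwidth", "qual"),
                               tag = c("CB", "GN", "TR"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  qs <- as(x$qual, "IntegerList")
  res <- c(all_primary = 0L, barcode_matched = 0L, gene_tagged = 0L,
           transcript_tagged = 0L)
  for (i in seq_along(x$flag)) {
    f <- x$flag[i]
    if (bitwAnd(f, 256L) != 0L || bitwAnd(f, 2048L) != 0L) next
    q <- qs[[i]]
    if (length(q) == 0 || mean(q) <= min_q) next
    res["all_primary"] <- res["all_primary"] + 1L
    cb <- x$tag$CB[i]
    bc_ok <- !is.na(cb) && cb %in% whitelist
    if (bc_ok) res["barcode_matched"] <- res["barcode_matched"] + 1L
    gn <- x$tag$GN[i]; tr <- x$tag$TR[i]
    if (bc_ok && !is.na(gn) && gn != "-") res["gene_tagged"] <- res["gene_tagged"] + 1L
    if (bc_ok && !is.na(tr) && tr != "-") res["transcript_tagged"] <- res["transcript_tagged"] + 1L
  }
  res
}

# Per-base increment pileup.
naive_coverage <- function(starts, ends, L) {
  cov <- integer(L)
  for (i in seq_along(starts)) {
    for (p in starts[i]:min(ends[i], L)) cov[p] <- cov[p] + 1L
  }
  cov
}

# Bin-mean rescale, coded independently of rescale_to_100.
naive_rescale <- function(cov) {
  L <- length(cov)
  out <- rep(NA_real_, 100)
  for (b in 0:99) {
    vals <- cov[which(floor((seq_len(L) - 1) * 100 / L) == b)]
    if (length(vals)) out[b + 1] <- sum(vals) / length(vals)
  }
  out
}

# Double-loop pseudobulk.
naive_pseudobulk <- function(counts, groups) {
  gl <- sort(unique(groups))
  out <- matrix(0, nrow(counts), length(gl), dimnames = list(rownames(counts), gl))
  for (j in seq_len(ncol(counts))) {
    g <- groups[colnames(counts)[j]]
    for (i in seq_len(nrow(counts))) out[i, g] <- out[i, g] + counts[i, j]
  }
  out
}

# Pairwise-count confusion matrix.
naive_confusion <- function(la, lb) {
  common <- intersect(names(la), names(lb))
  ra <- sort(unique(la[common])); rb <- sort(unique(lb[common]))
  out <- matrix(0L, length(ra), length(rb), dimnames = list(ra, rb))
  for (bc in common) out[la[[bc]], lb[[bc]]] <- out[la[[bc]], lb[[bc]]] + 1L
  out
}

# Exhaustive rule-table classifier: enumerate region membership and decide
# from the table of occupied regions. Independent of classify_transcript.
oracle_classify <- function(rel, strict = FALSE) {
  if (length(rel) == 0) return("none")
  regions <- vapply(rel, function(r) {
    if (r < 0.25) "5" else if (r >= 0.75) "3" else "C"
  }, character(1))
  key <- paste(sort(unique(regions)), collapse = "")
  if (!strict) {
    switch(key,
           "5" = "five_prime", "3" = "three_prime", "C" = "central",
           "35" = "both_ends", "5C" = "five_prime", "3C" = "three_prime",
           "35C" = "both_ends")
  } else {
    switch(key,
           "5" = "five_prime", "3" = "three_prime", "C" = "central",
           "35" = "five_prime+three_prime",
           "5C" = "five_prime+central", "3C" = "central+three_prime",
           "35C" = "five_prime+central+three_prime")
  }
}

labels_of <- function(cells, col) stats::setNames(cells[[col]], cells$barcode)
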