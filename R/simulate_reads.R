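#' Describe a simulated library chemistry
#'
#' A `library_profile` parameterises how reads are generated from a
#' transcriptome: which transcript end the chemistry anchors at, how much of
#' the molecule survives (a truncated Normal on retained length, measured
#' from the capture end), how often internal priming overrides the anchor
#' (the read then starts at a uniform internal position and runs to the 3'
#' end), which cell barcodes exist, and how often the upstream pipeline
#' manages to assign a gene or a transcript tag to a read.
#'
#' @param capture_end `"five_prime"` or `"three_prime"`.
#' @param truncation_mean_bp,truncation_sd_bp Normal parameters of retained
#'   read length (bp), clipped to `[1, spliced length]`.
#' @param internal_priming_rate probability a read starts at a uniform
#'   internal position and runs to the 3' end, ignoring `capture_end`.
#' @param barcode_whitelist character vector of cell barcodes.
#' @param gene_tag_rate,transcript_tag_rate marginal probabilities that a
#'   read carries a gene / transcript tag; a transcript tag is only ever
#'   emitted together with a gene tag, so
#'   `transcript_tag_rate <= gene_tag_rate` is required.
#' @param dominant_gene_id,dominant_gene_fraction optionally route a fixed
#'   expected fraction of reads to one gene (a highly-expressed-gene
#'   scenario such as insulin in pancreatic islets).
#' @param umi_collision_rate probability a read reuses an already-seen UMI
#'   of its barcode instead of receiving a fresh one (default 0: UMIs
#'   unique per read).
#' @param base_qscore constant phred score written for every base
#'   (default 12; set below 8 to exercise the mean-quality read filter).
#' @param seed integer seed for the simulation RNG.
#' @return a `library_profile` list.
#' @export
library_profile <- function(capture_end = c("three_prime", "five_prime"),
                            truncation_mean_bp = 600,
                            truncation_sd_bp = 150,
                            internal_priming_rate = 0,
                            barcode_whitelist = sprintf("BC%04d", 1:96),
                            gene_tag_rate = 1,
                            transcript_tag_rate = 1,
                            dominant_gene_id = NULL,
                            dominant_gene_fraction = 0,
                            umi_collision_rate = 0,
                            base_qscore = 12,
                            seed = 1) {
  capture_end <- match.arg(capture_end)
  stopifnot(truncation_mean_bp > 0, truncation_sd_bp >= 0,
            internal_priming_rate >= 0, internal_priming_rate <= 1,
            length(barcode_whitelist) >= 1,
            umi_collision_rate >= 0, umi_collision_rate < 1,
            base_qscore >= 0, base_qscore <= 60)
  if (!(gene_tag_rate >= 0 && gene_tag_rate <= 1 &&
        transcript_tag_rate >= 0 && transcript_tag_rate <= gene_tag_rate))
    stop("tag rates must satisfy 0 <= transcript_tag_rate <= gene_tag_rate <= 1")
  if (dominant_gene_fraction < 0 || dominant_gene_fraction > 1)
    stop("dominant_gene_fraction must be in [0, 1]")
  if (dominant_gene_fraction > 0 && is.null(dominant_gene_id))
    stop("dominant_gene_fraction > 0 requires dominant_gene_id")
  structure(list(capture_end = capture_end,
                 truncation_mean_bp = truncation_mean_bp,
                 truncation_sd_bp = truncation_sd_bp,
                 internal_priming_rate = internal_priming_rate,
                 barcode_whitelist = barcode_whitelist,
                 gene_tag_rate = gene_tag_rate,
                 transcript_tag_rate = transcript_tag_rate,
                 dominant_gene_id = dominant_gene_id,
                 dominant_gene_fraction = dominant_gene_fraction,
                 umi_collision_rate = umi_collision_rate,
                 base_qscore = base_qscore,
                 seed = seed),
            class = "library_profile")
}

#' Simulate a tagged transcript-space BAM with ground truth
#'
#' Draws `n_reads` reads from `txome` under `profile`. Reads are written as
#' pre-aligned records against the transcriptome itself (one reference
#' sequence per transcript, ungapped `M` alignments in spliced-mRNA
#' coordinates), carrying barcode (`CB`), UMI (`UB`) and — at the profile's
#' rates — gene (`GN`) and transcript (`TR`) tags. A transcript tag is only
#' emitted together with a gene tag. The BAM is coordinate-sorted and
#' indexed. The returned truth table has one row per emitted record.
#'
#' @param txome a [as_transcriptome()] object.
#' @param profile a [library_profile()].
#' @param n_reads number of reads to draw.
#' @param expression_weights optional named non-negative vector over
#'   transcripts (relative expression). Default: lognormal(0, 1) draws from
#'   the profile RNG, emulating a skewed expression distribution.
#' @param bam output BAM path (without or with `.bam`); its `.bai` index is
#'   written next to it.
#' @param write_bam set `FALSE` to skip BAM serialisation and return the
#'   truth table only; the RNG stream is identical either way.
#' @return list with `bam` (path or `NA`) and `truth`, a tibble with
#'   columns `read_id`, `transcript_id`, `gene_id`, `length` (query bp),
#'   `start`, `end` (0-based half-open transcript coordinates), `barcode`,
#'   `umi`, `gene_tag`, `transcript_tag` (logical: tag emitted),
#'   `internal_priming`.
#' @export
simulate_reads <- function(txome, profile, n_reads,
                           expression_weights = NULL,
                           bam = tempfile(fileext = ".bam"),
                           write_bam = TRUE) {
  stopifnot(is(profile, "library_profile"), n_reads >= 1)
  lens <- tx_lengths(txome)
  map <- tx2gene(txome)
  txs <- names(lens)
  if (!is.null(profile$dominant_gene_id) &&
      !profile$dominant_gene_id %in% map)
    stop("dominant_gene_id '", profile$dominant_gene_id, "' not in transcriptome")

  truth <- with_seed(profile$seed, {
    w <- expression_weights %||%
      setNames(stats::rlnorm(length(txs)), txs)
    if (is.null(names(w)) || !all(txs %in% names(w)))
      stop("expression_weights must be named for every transcript")
    w <- w[txs]
    if (any(w < 0) || sum(w) <= 0) stop("expression weights must be non-negative and sum > 0")

    f <- profile$dominant_gene_fraction
    if (!is.null(profile$dominant_gene_id) && f > 0) {
      dom_tx <- txs[map[txs] == profile$dominant_gene_id]
      oth_tx <- setdiff(txs, dom_tx)
      w_dom <- w[dom_tx]; if (sum(w_dom) <= 0) w_dom[] <- 1
      from_dom <- runif(n_reads) < f
      tx <- character(n_reads)
      tx[from_dom] <- sample(dom_tx, sum(from_dom), replace = TRUE,
                             prob = w_dom)
      if (length(oth_tx) == 0) tx[!from_dom] <- sample(dom_tx, sum(!from_dom), TRUE, w_dom)
      else {
        w_oth <- w[oth_tx]; if (sum(w_oth) <= 0) w_oth[] <- 1
        tx[!from_dom] <- sample(oth_tx, sum(!from_dom), replace = TRUE, prob = w_oth)
      }
    } else {
      tx <- sample(txs, n_reads, replace = TRUE, prob = w)
    }
    L <- lens[tx]

    ip <- runif(n_reads) < profile$internal_priming_rate
    rl <- pmin(pmax(round(rnorm(n_reads, profile$truncation_mean_bp,
                                profile$truncation_sd_bp)), 1L), L)
    # anchored reads cover the capture end; internally primed reads start
    # uniformly and run to the 3' end
    start <- integer(n_reads)
    if (profile$capture_end == "five_prime") {
      start[!ip] <- 0L
    } else {
      start[!ip] <- as.integer(L[!ip] - rl[!ip])
    }
    if (any(ip)) {
      start[ip] <- as.integer(floor(runif(sum(ip)) * L[ip]))
      rl[ip] <- as.integer(L[ip] - start[ip])
    }
    end <- as.integer(start + rl)

    barcode <- sample(profile$barcode_whitelist, n_reads, replace = TRUE)
    umi <- sprintf("UMI%08d", seq_len(n_reads))
    if (profile$umi_collision_rate > 0) {
      collide <- which(runif(n_reads) < profile$umi_collision_rate)
      for (i in collide) {
        prev <- which(barcode[seq_len(i - 1L)] == barcode[i])
        if (length(prev)) umi[i] <- umi[sample(prev, 1L)]
      }
    }

    g <- profile$gene_tag_rate
    t <- profile$transcript_tag_rate
    gene_tag <- runif(n_reads) < g
    # conditional rate t/g gives marginal transcript-tag rate t with nesting
    transcript_tag <- gene_tag & (if (g > 0) runif(n_reads) < t / g else FALSE)

    tibble(read_id = sprintf("read%07d", seq_len(n_reads)),
           transcript_id = tx, gene_id = unname(map[tx]),
           length = as.integer(rl), start = start, end = end,
           barcode = barcode, umi = umi,
           gene_tag = gene_tag, transcript_tag = transcript_tag,
           internal_priming = ip)
  })

  out_bam <- NA_character_
  if (write_bam) {
    out_bam <- write_tagged_bam(truth, lens, profile$base_qscore, bam)
  }
  list(bam = out_bam, truth = truth)
}

# Serialise a truth table as a coordinate-sorted, indexed transcript-space BAM.
write_tagged_bam <- function(truth, lens, base_qscore, bam) {
  qchar <- rawToChar(as.raw(as.integer(base_qscore) + 33L))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), unname(lens)))
  recs <- sprintf(
    "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s%s%s",
    truth$read_id, truth$transcript_id, truth$start + 1L, truth$length,
    strrep("A", truth$length), strrep(qchar, truth$length),
    truth$barcode, truth$umi,
    ifelse(truth$gene_tag, paste0("\tGN:Z:", truth$gene_id), ""),
    ifelse(truth$transcript_tag, paste0("\tTR:Z:", truth$transcript_id), ""))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(c(header, recs), sam)
  dest <- sub("\\.bam$", "", bam)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
}
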