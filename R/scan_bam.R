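#' Scan a tagged BAM into a read table
#'
#' Streams a BAM (or SAM converted upstream) and returns one row per primary
#' record whose mean base quality exceeds `min_qscore` — the standard
#' nanopore read-quality pre-filter, applied strictly (`> min_qscore`).
#' Secondary (0x100) and supplementary (0x800) records are dropped, so read
#' lengths reflect full query sequences, not hard-clipped fragments.
#' Records without stored base qualities have undefined mean quality and are
#' excluded by the filter.
#'
#' @param bam path to a BAM file. A missing index is tolerated (sequential
#'   scan).
#' @param barcode_set optional character vector of retained cell barcodes.
#'   When given, `barcode_matched` is `TRUE` iff the barcode tag value is in
#'   the set; when `NULL`, any non-sentinel barcode tag counts as matched.
#' @param min_qscore mean per-base phred threshold; reads must be strictly
#'   above it (default 7).
#' @param tags named character vector mapping roles to BAM tag names;
#'   default `c(bc = "CB", umi = "UB", gene = "GN", tx = "TR")`.
#' @param sentinels tag values treated as absent (default `"-"` and `""`).
#' @return a tibble with columns `qname`, `ref`, `pos` (1-based alignment
#'   start), `ref_end` (1-based inclusive alignment end on the reference),
#'   `query_length`, `mean_qual`, `barcode`, `umi`, `gene`, `transcript`,
#'   `barcode_matched`. Unmapped primaries keep `NA` for `ref`/`pos`.
#' @export
scan_bam <- function(bam, barcode_set = NULL, min_qscore = 7,
                     tags = c(bc = "CB", umi = "UB", gene = "GN", tx = "TR"),
                     sentinels = c("-", "")) {
  stopifnot(all(c("bc", "umi", "gene", "tx") %in% names(tags)))
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar", "qual"),
    tag = unname(tags[c("bc", "umi", "gene", "tx")]))
  x <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                error = function(e) stop("unreadable BAM '", bam, "': ", conditionMessage(e)))
  if (!length(x$flag)) {
    return(empty_read_table())
  }
  primary <- bitwAnd(x$flag, 0x100L) == 0L & bitwAnd(x$flag, 0x800L) == 0L
  mq <- rep(NA_real_, length(x$flag))
  qlist <- as(x$qual, "IntegerList")
  has_q <- lengths(qlist) > 0
  mq[has_q] <- vapply(qlist[has_q], mean, numeric(1))

  keep <- primary & !is.na(mq) & mq > min_qscore
  clean_tag <- function(v) {
    if (is.null(v)) return(rep(NA_character_, sum(keep)))
    v <- v[keep]
    v[!is.na(v) & v %in% sentinels] <- NA_character_
    v
  }
  cig <- x$cigar[keep]
  refw <- rep(NA_integer_, sum(keep))
  has_aln <- !is.na(cig)
  refw[has_aln] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig[has_aln])
  pos <- x$pos[keep]
  reads <- tibble(
    qname = x$qname[keep],
    ref = as.character(x$rname)[keep],
    pos = pos,
    ref_end = pos + refw - 1L,
    query_length = x$qwidth[keep],
    mean_qual = mq[keep],
    barcode = clean_tag(x$tag[[tags[["bc"]]]]),
    umi = clean_tag(x$tag[[tags[["umi"]]]]),
    gene = clean_tag(x$tag[[tags[["gene"]]]]),
    transcript = clean_tag(x$tag[[tags[["tx"]]]])
  )
  reads$barcode_matched <- if (is.null(barcode_set)) !is.na(reads$barcode)
                           else !is.na(reads$barcode) & reads$barcode %in% barcode_set
  n_orphan <- sum(!is.na(reads$transcript) & is.na(reads$gene))
  if (n_orphan > 0)
    warning(n_orphan, " read(s) carry a transcript tag without a gene tag")
  reads
}

empty_read_table <- function() {
  tibble(qname = character(), ref = character(), pos = integer(),
         ref_end = integer(), query_length = integer(), mean_qual = numeric(),
         barcode = character(), umi = character(), gene = character(),
         transcript = character(), barcode_matched = logical())
}
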