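#' Deduplicate reads by cell barcode and UMI
#'
#' Restricts a read table to retained cells and keeps a single read per
#' (barcode, UMI) pair — the molecule-level view used for coverage
#' metaplots. Within a duplicate group the read with the longest reference
#' alignment span wins; ties keep the first read in scan (coordinate)
#' order. Reads lacking a barcode or UMI cannot be grouped and are dropped.
#'
#' @param reads a read table from [scan_bam()].
#' @param cells optional character vector of retained cell barcodes; when
#'   given, reads from other barcodes are dropped first.
#' @return the deduplicated read tibble, in the original scan order.
#' @export
dedup_reads <- function(reads, cells = NULL) {
  if (nrow(reads) > 0 && all(is.na(reads$umi)))
    stop("no read carries a UMI tag: cannot deduplicate")
  r <- reads %>% mutate(.row = row_number()) %>%
    filter(!is.na(.data$barcode), !is.na(.data$umi))
  if (!is.null(cells)) r <- r %>% filter(.data$barcode %in% cells)
  r <- r %>%
    mutate(.span = .data$ref_end - .data$pos + 1L) %>%
    group_by(.data$barcode, .data$umi) %>%
    slice(which.max(.data$.span)) %>%   # first max = first in scan order on ties
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row", -".span")
  r
}

#' Per-transcript base-level coverage
#'
#' Counts, for every transcript in the annotation and every spliced-mRNA
#' position, how many reads' alignments cover that position (standard
#' pileup semantics over the reference span of each transcript-space
#' alignment). Transcripts without reads get all-zero vectors; reads whose
#' reference is absent from the annotation are excluded and counted in the
#' `unassigned` attribute.
#'
#' @param reads a (typically deduplicated) read table aligned in transcript
#'   space, i.e. `ref` is a transcript id.
#' @param txome a [as_transcriptome()] object, or a named vector of spliced
#'   transcript lengths.
#' @return named list of integer vectors (one per transcript, length =
#'   spliced length), with attribute `unassigned` = number of excluded
#'   reads.
#' @export
transcript_coverage <- function(reads, txome) {
  lens <- if (is.numeric(txome)) txome else tx_lengths(txome)
  r <- reads %>% filter(!is.na(.data$ref), !is.na(.data$pos))
  known <- r$ref %in% names(lens)
  if (any(!known))
    message(sum(!known), " read(s) reference transcripts absent from the annotation; excluded")
  r <- r[known, , drop = FALSE]
  by_tx <- split(r[c("pos", "ref_end")], factor(r$ref, levels = names(lens)))
  cov <- lapply(names(lens), function(tx) {
    d <- by_tx[[tx]]
    L <- lens[[tx]]
    if (is.null(d) || nrow(d) == 0) return(integer(L))
    ir <- IRanges::IRanges(start = d$pos, end = pmin(d$ref_end, L))
    as.integer(IRanges::coverage(ir, width = L))
  })
  names(cov) <- names(lens)
  attr(cov, "unassigned") <- sum(!known)
  cov
}

#' Rescale a per-base coverage vector to 100 relative positions
#'
#' Base `p` (0-based) of a length-`L` transcript maps to bin
#' `floor(p * 100 / L)`; each bin's value is the mean of its constituent
#' base coverages. For transcripts shorter than 100 bp some bins receive no
#' base; these inherit by linear interpolation between their nearest
#' occupied neighbours (flat extrapolation at the ends).
#'
#' @param cov numeric per-base coverage vector (5'->3').
#' @return numeric vector of length 100.
#' @export
rescale_to_100 <- function(cov) {
  L <- length(cov)
  if (L < 1) stop("coverage vector must have length >= 1")
  bin <- floor((seq_len(L) - 1) * 100 / L)  # 0..99
  means <- tapply(cov, factor(bin, levels = 0:99), mean)
  v <- as.numeric(means)
  if (anyNA(v)) {
    occ <- which(!is.na(v))
    v <- approx(occ, v[occ], xout = 1:100, rule = 2)$y
  }
  v
}

#' Assemble a raw coverage matrix over multi-exon transcripts
#'
#' Stacks [rescale_to_100()] rows for every transcript with more than one
#' exon — single-exon transcripts are excluded because relative-position
#' coverage of unspliced transcripts conflates priming artifacts with
#' annotation differences. The matrix carries a normalisation `stage`
#' attribute (`"raw"` here) that the downstream transforms check and
#' advance, so each transform can only be applied once and in order.
#'
#' @param cov a coverage list from [transcript_coverage()].
#' @param txome the matching [as_transcriptome()] object.
#' @param min_exons minimum exon count for inclusion (default 2).
#' @return a `coverage_matrix`: transcripts x 100 numeric matrix with
#'   attribute `stage = "raw"`.
#' @export
coverage_matrix <- function(cov, txome, min_exons = 2) {
  nex <- tx_exon_counts(txome)
  keep <- names(cov)[names(cov) %in% names(nex)[nex >= min_exons]]
  if (length(keep) == 0) stop("no transcript with >= ", min_exons, " exons")
  m <- do.call(rbind, lapply(cov[keep], rescale_to_100))
  rownames(m) <- keep
  structure(m, stage = "raw", class = c("coverage_matrix", "matrix", "array"))
}

coverage_stage <- function(m) attr(m, "stage") %||% "raw"

#' Depth-normalise and softmax-transform a coverage matrix
#'
#' The two-step normalisation behind the coverage metaplots: every entry is
#' first divided by the library's retained read count (depth
#' normalisation), then each transcript row is passed through a softmax so
#' it sums to 1. The order matters — softmax is not scale-invariant, so
#' depth normalisation changes the softmax output — and is enforced via the
#' matrix's `stage` attribute; re-applying a transform raises an error.
#' All-zero rows softmax to the uniform row (each entry 1/100) and are
#' recorded in the `zero_rows` attribute.
#'
#' @param m a `coverage_matrix`.
#' @param total_reads positive read-depth denominator (retained reads in
#'   the sample).
#' @return the transformed `coverage_matrix` with `stage = "softmax"`.
#' @export
normalize_and_softmax <- function(m, total_reads) {
  softmax_transform(depth_normalize(m, total_reads))
}

#' @rdname normalize_and_softmax
#' @export
depth_normalize <- function(m, total_reads) {
  if (coverage_stage(m) != "raw")
    stop("depth_normalize expects stage 'raw', got '", coverage_stage(m), "'")
  if (!is.numeric(total_reads) || total_reads <= 0) stop("total_reads must be > 0")
  out <- m / total_reads
  attr(out, "stage") <- "depth_normalized"
  out
}

#' @rdname normalize_and_softmax
#' @export
softmax_transform <- function(m) {
  if (coverage_stage(m) != "depth_normalized")
    stop("softmax_transform expects stage 'depth_normalized', got '", coverage_stage(m), "'")
  zero <- rownames(m)[rowSums(m != 0) == 0]
  e <- exp(m - apply(m, 1, max))  # max-shift for numerical stability
  out <- e / rowSums(e)
  attributes(out) <- attributes(m)
  attr(out, "stage") <- "softmax"
  attr(out, "zero_rows") <- zero
  out
}

#' Meta-coverage curve over a transcript subset
#'
#' Column means of a softmax-stage coverage matrix over transcripts passing
#' exon-count and length filters — one value per relative position 1..100,
#' summing to 1. This is the per-sample metagene curve whose shape
#' distinguishes 5'-anchored from 3'-anchored chemistries and exposes
#' internal priming as central enrichment.
#'
#' @param m a softmax-stage `coverage_matrix`.
#' @param txome the matching [as_transcriptome()] object.
#' @param min_exons minimum exon count (default 2, i.e. >1 exon).
#' @param exon_at_least optional stricter exon-count filter (e.g. 9).
#' @param length_band optional `c(lo, hi)` spliced-length band in bp
#'   (inclusive).
#' @return a tibble (`position` 1..100, `value`) of class `meta_coverage`
#'   with attributes `n_transcripts` and `filters`.
#' @export
meta_coverage <- function(m, txome, min_exons = 2, exon_at_least = NULL,
                          length_band = NULL) {
  if (coverage_stage(m) != "softmax")
    stop("meta_coverage expects a softmax-stage coverage matrix")
  nex <- tx_exon_counts(txome)[rownames(m)]
  lens <- tx_lengths(txome)[rownames(m)]
  keep <- nex >= max(min_exons, 2)
  filt <- sprintf("exons >= %d", max(min_exons, 2))
  if (!is.null(exon_at_least)) {
    keep <- keep & nex >= exon_at_least
    filt <- c(filt, sprintf("exons >= %d", exon_at_least))
  }
  if (!is.null(length_band)) {
    stopifnot(length(length_band) == 2, length_band[1] <= length_band[2])
    keep <- keep & lens >= length_band[1] & lens <= length_band[2]
    filt <- c(filt, sprintf("length in [%d, %d]", length_band[1], length_band[2]))
  }
  if (!any(keep))
    stop("no transcript passes the filters: ", paste(filt, collapse = "; "))
  v <- colMeans(m[keep, , drop = FALSE])
  out <- tibble(position = 1:100, value = as.numeric(v))
  attr(out, "n_transcripts") <- sum(keep)
  attr(out, "filters") <- filt
  class(out) <- c("meta_coverage", class(out))
  out
}

#' Plot a set of meta-coverage curves
#'
#' @param curves named list of [meta_coverage()] tibbles (name = sample).
#' @return a ggplot object.
#' @export
plot_meta_coverage <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- bind_rows(lapply(names(curves), function(nm)
    mutate(as_tibble(curves[[nm]]), sample = nm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative transcript position (5' -> 3')",
                  y = "mean softmax coverage") +
    ggplot2::theme_minimal()
}
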