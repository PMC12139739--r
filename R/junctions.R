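#' Extract splice junctions in transcript coordinates
#'
#' One row per exon-exon boundary of every multi-exon transcript. The
#' transcript-coordinate `position` is the offset of the first base of the
#' downstream-in-mRNA exon in the spliced transcript (0-based), so
#' `0 < position < spliced length`. For minus-strand transcripts the mRNA
#' order is the reverse of genomic order, and positions are computed in
#' mRNA orientation (position 0 = the 5' cap end). The `genomic_key`
#' (chrom:donor-acceptor:strand, coordinates of the skipped intron) is
#' identical for the same splice event wherever it recurs, which is what
#' makes junction uniqueness well defined across a gene's isoforms.
#'
#' @param txome a [as_transcriptome()] object.
#' @return tibble: `gene_id`, `transcript_id`, `position`, `genomic_key`.
#' @export
extract_junctions <- function(txome) {
  res <- txome %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(
      n_exon = n(),
      # genomic intron bounds between genomically adjacent exons
      donor = list(.data$end[-n()]), acceptor = list(.data$start[-1]),
      elen = list(.data$end - .data$start),
      .groups = "drop"
    ) %>%
    filter(.data$n_exon > 1)
  if (nrow(res) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  position = integer(), genomic_key = character()))
  }
  rows <- lapply(seq_len(nrow(res)), function(i) {
    elen <- res$elen[[i]]
    k <- length(elen) - 1L
    if (res$strand[i] == "+") {
      pos <- cumsum(elen)[seq_len(k)]
      don <- res$donor[[i]]; acc <- res$acceptor[[i]]
    } else {
      # mRNA order reverses genomic order; junction j in mRNA order sits
      # after the first j exons counted from the genomically last one
      pos <- cumsum(rev(elen))[seq_len(k)]
      don <- rev(res$donor[[i]]); acc <- rev(res$acceptor[[i]])
    }
    tibble(gene_id = res$gene_id[i], transcript_id = res$transcript_id[i],
           position = as.integer(pos),
           genomic_key = sprintf("%s:%d-%d:%s", res$chrom[i], don, acc, res$strand[i]))
  })
  bind_rows(rows)
}

#' Flag isoform-defining (unique) junctions
#'
#' A junction is unique to a transcript iff its genomic key occurs in no
#' other transcript of the same gene; observing such a junction in a read
#' identifies the isoform. All junctions of a single-transcript gene are
#' unique by definition. Uniqueness is scoped within the gene — sharing a
#' genomic junction with another gene does not remove isoform-defining
#' status.
#'
#' @param junctions output of [extract_junctions()].
#' @return the same tibble with a logical `is_unique` column.
#' @export
unique_junctions <- function(junctions) {
  junctions %>%
    group_by(.data$gene_id, .data$genomic_key) %>%
    mutate(is_unique = dplyr::n_distinct(.data$transcript_id) == 1) %>%
    ungroup()
}

junction_region <- function(r) {
  # half-open boundaries: r < 0.25 is 5', r >= 0.75 is 3', else central
  ifelse(r < 0.25, "five_prime", ifelse(r >= 0.75, "three_prime", "central"))
}

#' Classify one transcript's unique-junction positions
#'
#' Bins a transcript by where its isoform-defining junctions fall along the
#' spliced mRNA: the first 25% is the 5' region, the last 25% the 3'
#' region, the rest central. A transcript with unique junctions in both end
#' regions is `both_ends`; with unique junctions in exactly one end region
#' it takes that end's bin (end regions take precedence over central, which
#' acts as the residual category); junctions only in the middle give
#' `central`; no unique junctions give `none`. With `strict = TRUE` no
#' precedence is applied and the label is the `+`-joined list of occupied
#' regions (e.g. `"five_prime+central"`).
#'
#' @param positions transcript-coordinate junction positions (bp) of the
#'   transcript's unique junctions (may be empty).
#' @param length spliced transcript length (bp, >= 1).
#' @param strict emit composite multi-region labels instead of applying
#'   end-region precedence.
#' @return a single bin label.
#' @export
classify_transcript <- function(positions, length, strict = FALSE) {
  stopifnot(length >= 1)
  if (length(positions) == 0) return("none")
  reg <- junction_region(positions / length)
  has5 <- "five_prime" %in% reg
  has3 <- "three_prime" %in% reg
  hasC <- "central" %in% reg
  if (strict) {
    return(paste(c("five_prime", "central", "three_prime")[c(has5, hasC, has3)],
                 collapse = "+"))
  }
  if (has5 && has3) "both_ends"
  else if (has5) "five_prime"
  else if (has3) "three_prime"
  else "central"
}

#' Classify every transcript of an annotation
#'
#' Runs [extract_junctions()], [unique_junctions()] and
#' [classify_transcript()] over a whole transcriptome.
#'
#' @param txome a [as_transcriptome()] object.
#' @param strict passed to [classify_transcript()].
#' @return tibble: `transcript_id`, `gene_id`, `length`, `n_unique`,
#'   `bin`, `unique_rel_positions` (list column of positions / length).
#' @export
classify_transcripts <- function(txome, strict = FALSE) {
  lens <- tx_lengths(txome)
  uj <- unique_junctions(extract_junctions(txome))
  txs <- txome %>% distinct(.data$transcript_id, .data$gene_id)
  rows <- lapply(seq_len(nrow(txs)), function(i) {
    tid <- txs$transcript_id[i]
    p <- uj$position[uj$transcript_id == tid & uj$is_unique]
    L <- lens[[tid]]
    tibble(transcript_id = tid, gene_id = txs$gene_id[i],
           length = L, n_unique = length(p),
           bin = classify_transcript(p, L, strict = strict),
           unique_rel_positions = list(p / L))
  })
  bind_rows(rows)
}

#' Tabulate junction-bias bins
#'
#' Counts (or expression-weights) transcripts per bias bin. A library with
#' no strong end bias shows comparable `five_prime` and `three_prime`
#' fractions.
#'
#' @param classifications output of [classify_transcripts()].
#' @param weights optional named numeric vector of per-transcript weights
#'   (e.g. read counts); unweighted counting when `NULL`. Transcripts
#'   missing from `weights` get weight 0.
#' @return tibble: `bin`, `n` (count or total weight), `fraction`. All five
#'   canonical bins are always present (composites too, in strict mode).
#' @export
bias_table <- function(classifications, weights = NULL) {
  if (nrow(classifications) == 0) stop("no classified transcripts")
  w <- if (is.null(weights)) rep(1, nrow(classifications))
       else {
         v <- weights[classifications$transcript_id]
         ifelse(is.na(v), 0, v)
       }
  bins <- union(c("five_prime", "three_prime", "central", "both_ends", "none"),
                unique(classifications$bin))
  agg <- tapply(w, factor(classifications$bin, levels = bins), sum)
  agg[is.na(agg)] <- 0
  tot <- sum(agg)
  tibble(bin = bins, n = as.numeric(agg),
         fraction = if (tot > 0) as.numeric(agg) / tot else NA_real_)
}
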