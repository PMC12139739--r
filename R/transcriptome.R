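#' Transcript models as an exon table
#'
#' A `transcriptome` is a tibble with one row per exon and columns
#' `gene_id`, `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`,
#' `end` (0-based, half-open genomic coordinates) and `exon_rank`
#' (genomic order within the transcript). Exons of a transcript are
#' non-overlapping and sorted by genomic start. Transcript coordinates used
#' throughout the package run 5'->3' along the spliced mRNA: for a
#' minus-strand transcript, transcript position 0 is the end of the
#' genomically last exon.
#'
#' @param exons a data frame with the columns above (`exon_rank` optional;
#'   recomputed from genomic order).
#' @return a validated `transcriptome` tibble.
#' @export
as_transcriptome <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("missing transcriptome columns: ", paste(miss, collapse = ", "))
  ex <- as_tibble(exons) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup()
  if (!all(ex$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(ex$end <= ex$start)) stop("exons must have end > start (0-based half-open)")
  bad <- ex %>%
    group_by(.data$transcript_id) %>%
    summarise(ov = any(.data$start[-1] < .data$end[-n()]),
              mixed = dplyr::n_distinct(.data$strand) > 1 |
                dplyr::n_distinct(.data$chrom) > 1 |
                dplyr::n_distinct(.data$gene_id) > 1)
  if (any(bad$ov)) stop("overlapping exons in: ", paste(bad$transcript_id[bad$ov], collapse = ", "))
  if (any(bad$mixed)) stop("inconsistent strand/chrom/gene within a transcript")
  class(ex) <- c("transcriptome", class(ex))
  ex
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %d genes, %d transcripts, %d exons\n",
              length(unique(x$gene_id)), length(unique(x$transcript_id)), nrow(x)))
  NextMethod()
}

#' Spliced transcript lengths
#'
#' @param txome a [as_transcriptome()] object.
#' @return named integer vector, spliced length (bp) per transcript.
#' @export
tx_lengths <- function(txome) {
  s <- txome %>% group_by(.data$transcript_id) %>%
    summarise(len = sum(.data$end - .data$start))
  setNames(as.integer(s$len), s$transcript_id)
}

#' Exon counts per transcript
#' @inheritParams tx_lengths
#' @return named integer vector.
#' @export
tx_exon_counts <- function(txome) {
  s <- txome %>% count(.data$transcript_id)
  setNames(as.integer(s$n), s$transcript_id)
}

#' Transcript-to-gene map
#' @inheritParams tx_lengths
#' @return named character vector: `tx2gene(x)[transcript_id] == gene_id`.
#' @export
tx2gene <- function(txome) {
  s <- txome %>% distinct(.data$transcript_id, .data$gene_id)
  setNames(s$gene_id, s$transcript_id)
}

#' Generate a random toy transcriptome
#'
#' Builds a deterministic (given `seed`) multi-gene annotation in which each
#' gene owns a scaffold of exons and every transcript uses the first scaffold
#' exon plus a random subset of the rest. Consequently, whenever a gene has
#' two or more transcripts they share at least one exon, and skipped scaffold
#' exons create isoform-defining junctions. Both strands are represented
#' whenever `n_genes >= 2`.
#'
#' @param n_genes number of genes.
#' @param transcripts_per_gene length-2 integer range (inclusive).
#' @param exons_per_transcript length-2 integer range (inclusive).
#' @param exon_len,intron_len length-2 bp ranges (inclusive).
#' @param seed integer seed; identical seeds give identical annotations.
#' @return a `transcriptome` tibble.
#' @export
generate_transcriptome <- function(n_genes,
                                   transcripts_per_gene = c(1, 3),
                                   exons_per_transcript = c(1, 8),
                                   exon_len = c(80, 300),
                                   intron_len = c(60, 500),
                                   seed = 1) {
  chk_range <- function(r, nm, lo = 1) {
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < lo)
      stop("invalid range for ", nm, ": must be c(lo, hi) with lo <= hi and lo >= ", lo)
    as.integer(r)
  }
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  transcripts_per_gene <- chk_range(transcripts_per_gene, "transcripts_per_gene")
  exons_per_transcript <- chk_range(exons_per_transcript, "exons_per_transcript")
  exon_len <- chk_range(exon_len, "exon_len")
  intron_len <- chk_range(intron_len, "intron_len")

  rint <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else sample(seq(r[1], r[2]), n, replace = TRUE)

  with_seed(seed, {
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (n_genes >= 2 && length(unique(strands)) == 1)
      strands[n_genes] <- setdiff(c("+", "-"), strands[1])
    rows <- vector("list", n_genes)
    cursor <- 1000L
    for (g in seq_len(n_genes)) {
      gid <- sprintf("GENE%03d", g)
      n_tx <- rint(1, transcripts_per_gene)
      n_ex <- rint(n_tx, exons_per_transcript)
      k <- max(n_ex) + if (n_tx > 1L) 1L else 0L
      elens <- rint(k, exon_len)
      ilens <- rint(max(k - 1, 1), intron_len)
      starts <- cursor + c(0L, cumsum(elens[-k] + ilens[seq_len(k - 1)]))
      ends <- starts + elens
      cursor <- ends[k] + 10000L
      tx_rows <- lapply(seq_len(n_tx), function(i) {
        take <- if (n_ex[i] >= k) seq_len(k)
                else sort(c(1L, sample(2:k, n_ex[i] - 1L)))
        tibble(gene_id = gid,
               transcript_id = sprintf("%s.T%d", gid, i),
               chrom = sprintf("chr%d", (g - 1L) %% 3L + 1L),
               strand = strands[g],
               start = starts[take], end = ends[take])
      })
      rows[[g]] <- bind_rows(tx_rows)
    }
    as_transcriptome(bind_rows(rows))
  })
}

#' Write a transcriptome as an Ensembl-dialect GTF
#'
#' Emits `gene`, `transcript` and `exon` features with `gene_id`,
#' `transcript_id` and (for exons) `exon_number` attributes. Exon numbers
#' follow transcription order, so a minus-strand transcript's exon 1 is the
#' genomically last exon. Coordinates are 1-based inclusive per the GTF
#' standard. Output is byte-stable for a given transcriptome.
#'
#' @param txome a `transcriptome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(txome, path) {
  attr_str <- function(gid, tid = NULL, exn = NULL) {
    s <- sprintf('gene_id "%s";', gid)
    if (!is.null(tid)) s <- paste0(s, sprintf(' transcript_id "%s";', tid))
    if (!is.null(exn)) s <- paste0(s, sprintf(' exon_number "%d";', exn))
    s
  }
  lines <- character(0)
  genes <- txome %>% group_by(.data$gene_id) %>%
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end))
  txs <- txome %>% group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  fmt <- function(chrom, feat, s0, e0, strand, attrs)
    sprintf("%s\tsclrqc\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feat, s0 + 1L, e0, strand, attrs)
  for (g in seq_len(nrow(genes))) {
    gr <- genes[g, ]
    lines <- c(lines, fmt(gr$chrom, "gene", gr$start, gr$end, gr$strand, attr_str(gr$gene_id)))
    gtx <- txs[txs$gene_id == gr$gene_id, ]
    for (t in seq_len(nrow(gtx))) {
      tr <- gtx[t, ]
      lines <- c(lines, fmt(tr$chrom, "transcript", tr$start, tr$end, tr$strand,
                            attr_str(tr$gene_id, tr$transcript_id)))
      ex <- txome[txome$transcript_id == tr$transcript_id, ]
      ord <- if (tr$strand == "+") order(ex$start) else order(-ex$start)
      ex <- ex[ord, ]
      for (e in seq_len(nrow(ex)))
        lines <- c(lines, fmt(ex$chrom[e], "exon", ex$start[e], ex$end[e], ex$strand[e],
                              attr_str(tr$gene_id, tr$transcript_id, e)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation into a transcriptome
#'
#' Parses an Ensembl-dialect GTF via [rtracklayer::import()] and keeps the
#' exon features. Round-trips the output of [write_gtf()].
#'
#' @param path GTF file path.
#' @return a `transcriptome` tibble.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  as_transcriptome(tibble(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  ))
}
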