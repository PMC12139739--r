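#' Read-length summary by tag class
#'
#' Summarises query-sequence lengths for the nested read classes used to
#' judge a long-read single-cell library: all quality-passing primary reads,
#' those with a matched cell barcode, and — within the barcode-matched set —
#' those carrying a gene tag and those carrying a transcript tag. The mode
#' is reported as the midpoint of the modal histogram bin, since read-length
#' distributions are effectively continuous; ties go to the shortest bin.
#'
#' @param reads a read table from [scan_bam()].
#' @param bin_width histogram bin width in bp for the mode (default 50).
#' @return a tibble with one row per class: `class`, `n`, `mean_bp`,
#'   `median_bp`, `mode_bp`. Empty classes have `n = 0` and `NA` statistics.
#' @export
read_length_summary <- function(reads, bin_width = 50) {
  if (nrow(reads) == 0) stop("empty read stream: no quality-passing primary reads")
  stopifnot(bin_width >= 1)
  classes <- list(
    all_primary = rep(TRUE, nrow(reads)),
    barcode_matched = reads$barcode_matched,
    gene_tagged = reads$barcode_matched & !is.na(reads$gene),
    transcript_tagged = reads$barcode_matched & !is.na(reads$transcript)
  )
  bind_rows(lapply(names(classes), function(cl) {
    len <- reads$query_length[classes[[cl]]]
    if (length(len) == 0)
      return(tibble(class = cl, n = 0L, mean_bp = NA_real_,
                    median_bp = NA_real_, mode_bp = NA_real_))
    tibble(class = cl, n = length(len),
           mean_bp = mean(len), median_bp = median(len),
           mode_bp = modal_bin_midpoint(len, bin_width))
  }))
}

modal_bin_midpoint <- function(len, bin_width) {
  bins <- floor(len / bin_width)
  tab <- table(bins)
  modal <- as.integer(names(tab)[which.max(tab)])  # which.max: first max = smallest bin
  modal * bin_width + bin_width / 2
}

#' Gene / transcript identification rates
#'
#' Fraction of quality-passing primary reads assigned a gene tag, assigned a
#' transcript tag, or assigned neither — the per-library proportions used to
#' compare how well different chemistries support transcript-level analysis.
#' The three plotted categories (gene only, transcript, neither) partition
#' the read set.
#'
#' @inheritParams read_length_summary
#' @param cells_only restrict the denominator to barcode-matched reads
#'   (default `FALSE`: all quality-passing primary reads).
#' @return a one-row tibble: `n`, `frac_gene_identified`,
#'   `frac_transcript_identified`, `frac_gene_only`, `frac_neither`.
#' @export
identification_rates <- function(reads, cells_only = FALSE) {
  if (cells_only) reads <- reads[reads$barcode_matched, , drop = FALSE]
  if (nrow(reads) == 0) stop("empty read stream: cannot compute identification rates")
  has_g <- !is.na(reads$gene)
  has_t <- !is.na(reads$transcript)
  if (any(has_t & !has_g))
    warning(sum(has_t & !has_g), " read(s) transcript-tagged but not gene-tagged")
  n <- nrow(reads)
  tibble(n = n,
         frac_gene_identified = sum(has_g) / n,
         frac_transcript_identified = sum(has_t) / n,
         frac_gene_only = sum(has_g & !has_t) / n,
         frac_neither = sum(!has_g & !has_t) / n)
}

#' Fraction of reads from a target gene set
#'
#' Proportion of reads whose gene tag falls in `target_genes` — e.g. the
#' insulin genes Ins1/Ins2, which can consume a quarter of an islet
#' library's reads. The default denominator is all quality-passing primary
#' reads ("of the total reads"); `denominator = "gene_tagged"` restricts it
#' to reads that received any gene tag.
#'
#' @inheritParams read_length_summary
#' @param target_genes non-empty character vector of gene ids/symbols.
#' @param denominator `"all"` (default) or `"gene_tagged"`.
#' @return list with `fraction`, `n_target`, `n_total` and `per_gene`, a
#'   tibble (`gene`, `n`, `fraction`) over the target genes.
#' @export
gene_read_fraction <- function(reads, target_genes,
                               denominator = c("all", "gene_tagged")) {
  denominator <- match.arg(denominator)
  if (length(target_genes) == 0) stop("target_genes must be non-empty")
  n_total <- if (denominator == "all") nrow(reads) else sum(!is.na(reads$gene))
  hits <- !is.na(reads$gene) & reads$gene %in% target_genes
  per_gene <- tibble(gene = target_genes) %>%
    left_join(reads %>% filter(hits) %>% count(gene = .data$gene), by = "gene") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           fraction = if (n_total > 0) .data$n / n_total else NA_real_)
  list(fraction = if (n_total > 0) sum(hits) / n_total else NA_real_,
       n_target = sum(hits), n_total = n_total, per_gene = per_gene)
}

#' Depletion efficiency between a pre- and post-depletion library
#'
#' Quantifies how completely a targeted depletion (e.g. CRISPR/Cas9 removal
#' of insulin cDNA) removed the target genes, and whether anything else
#' moved. Efficiency is `1 - post_fraction / pre_fraction` over the target
#' set; the off-target table lists every other gene's read-fraction change,
#' ranked by absolute change, so a specific depletion shows near-zero
#' off-target shifts.
#'
#' @param pre,post read tables from [scan_bam()] for the libraries before
#'   and after depletion.
#' @param target_genes genes targeted by the depletion.
#' @param denominator passed to [gene_read_fraction()].
#' @return list of class `depletion_report`: `efficiency` (`NA` with a
#'   message when the pre-depletion fraction is 0), `pre_fraction`,
#'   `post_fraction`, and `off_target` (tibble: `gene`, `pre_fraction`,
#'   `post_fraction`, `delta`, ordered by `abs(delta)` descending).
#' @export
depletion_report <- function(pre, post, target_genes,
                             denominator = c("all", "gene_tagged")) {
  denominator <- match.arg(denominator)
  if (nrow(pre) == 0 || nrow(post) == 0) stop("pre and post read streams must be non-empty")
  pre_f <- gene_read_fraction(pre, target_genes, denominator)
  post_f <- gene_read_fraction(post, target_genes, denominator)
  eff <- if (is.na(pre_f$fraction) || pre_f$fraction == 0) NA_real_
         else 1 - post_f$fraction / pre_f$fraction
  if (is.na(eff)) message("pre-depletion target fraction is 0: efficiency undefined")
  frac_by_gene <- function(r) {
    n_tot <- if (denominator == "all") nrow(r) else sum(!is.na(r$gene))
    r %>% filter(!is.na(.data$gene)) %>% count(gene = .data$gene) %>%
      mutate(fraction = .data$n / n_tot) %>% select("gene", "fraction")
  }
  off <- dplyr::full_join(frac_by_gene(pre) %>% rename(pre_fraction = "fraction"),
                          frac_by_gene(post) %>% rename(post_fraction = "fraction"),
                          by = "gene") %>%
    filter(!.data$gene %in% target_genes) %>%
    mutate(pre_fraction = ifelse(is.na(.data$pre_fraction), 0, .data$pre_fraction),
           post_fraction = ifelse(is.na(.data$post_fraction), 0, .data$post_fraction),
           delta = .data$post_fraction - .data$pre_fraction) %>%
    arrange(dplyr::desc(abs(.data$delta)))
  structure(list(efficiency = eff,
                 pre_fraction = pre_f$fraction, post_fraction = post_f$fraction,
                 target_genes = target_genes, off_target = off),
            class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat(sprintf("<depletion_report> targets: %s\n", paste(x$target_genes, collapse = ", ")))
  cat(sprintf("  pre %.4f -> post %.4f; efficiency %s\n", x$pre_fraction, x$post_fraction,
              ifelse(is.na(x$efficiency), "undefined", sprintf("%.3f", x$efficiency))))
  cat(sprintf("  max |off-target shift|: %.5f\n",
              if (nrow(x$off_target)) max(abs(x$off_target$delta)) else 0))
  invisible(x)
}

#' One-sided rank-sum comparison of read lengths
#'
#' Wilcoxon rank-sum test on query lengths of two libraries (normal
#' approximation with tie correction, as appropriate for thousands of
#' integer lengths). The default alternative asks whether the second
#' library's reads are stochastically longer.
#'
#' @param reads_a,reads_b read tables from [scan_bam()], or bare numeric
#'   length vectors.
#' @param alternative `"second_longer"` (default), `"first_longer"` or
#'   `"two_sided"`.
#' @return the `htest` object from [stats::wilcox.test()].
#' @export
compare_read_lengths <- function(reads_a, reads_b,
                                 alternative = c("second_longer", "first_longer", "two_sided")) {
  alternative <- match.arg(alternative)
  la <- if (is.data.frame(reads_a)) reads_a$query_length else reads_a
  lb <- if (is.data.frame(reads_b)) reads_b$query_length else reads_b
  alt <- switch(alternative, second_longer = "greater",
                first_longer = "less", two_sided = "two.sided")
  wilcox.test(lb, la, alternative = alt, exact = FALSE, correct = TRUE)
}
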