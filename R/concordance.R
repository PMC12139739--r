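#' Pseudobulk aggregation by cell type and replicate
#'
#' Sums single-cell counts within every (cell type, replicate) group, so
#' replicates — not cells — become the units of downstream analysis.
#' Cells without a label (or replicate, when given) are excluded with a
#' warning; total counts over labelled cells are conserved exactly.
#'
#' @param counts features x cells matrix (base or `Matrix` sparse), with
#'   column names = cell barcodes.
#' @param cell_types named character vector: barcode -> cell-type label.
#' @param replicates optional named character vector: barcode -> replicate.
#'   When `NULL` groups are cell types alone.
#' @return features x groups base matrix; attribute `groups` is a tibble
#'   (`group`, `cell_type`, `replicate`, `n_cells`). Group names are
#'   `cell_type` or `cell_type:replicate`.
#' @export
pseudobulk <- function(counts, cell_types, replicates = NULL) {
  bcs <- colnames(counts)
  if (is.null(bcs)) stop("counts must have cell barcodes as column names")
  ct <- cell_types[bcs]
  rp <- if (is.null(replicates)) rep("", length(bcs)) else unname(replicates[bcs])
  miss <- is.na(ct) | (!is.null(replicates) & is.na(rp))
  if (any(miss))
    warning(sum(miss), " cell(s) lack a cell-type/replicate label; excluded")
  keep <- which(!miss)
  if (!length(keep)) stop("no labelled cells")
  grp <- if (is.null(replicates)) unname(ct[keep])
         else paste(ct[keep], rp[keep], sep = ":")
  gf <- factor(grp)
  ind <- Matrix::sparseMatrix(i = seq_along(keep), j = as.integer(gf),
                              x = 1, dims = c(length(keep), nlevels(gf)))
  pb <- as.matrix(counts[, keep, drop = FALSE] %*% ind)
  colnames(pb) <- levels(gf)
  meta <- tibble(group = grp, cell_type = unname(ct[keep]),
                 replicate = if (is.null(replicates)) NA_character_ else rp[keep]) %>%
    count(.data$group, .data$cell_type, .data$replicate, name = "n_cells") %>%
    arrange(.data$group)
  attr(pb, "groups") <- meta
  pb
}

#' Per-gene transcript-usage fractions
#'
#' For every (group, gene), the fraction of the gene's pseudobulk
#' expression carried by each of its transcripts — the quantity whose
#' between-cell-type change constitutes differential transcript usage.
#' Fractions within a (group, gene) sum to 1. Genes with zero counts in a
#' group are omitted (not zero-divided) and recorded in the `absent`
#' attribute.
#'
#' @param tx_pseudobulk transcripts x groups matrix (e.g. from
#'   [pseudobulk()] on the transcript-level counts).
#' @param tx_gene_map named character vector mapping every transcript id in
#'   the matrix to its gene (see [tx2gene()]).
#' @return long tibble of class `usage_fraction_table`: `group`, `gene_id`,
#'   `transcript_id`, `count`, `gene_total`, `fraction`.
#' @export
usage_fractions <- function(tx_pseudobulk, tx_gene_map) {
  txs <- rownames(tx_pseudobulk)
  if (is.null(txs)) stop("tx_pseudobulk must have transcript ids as row names")
  unmapped <- setdiff(txs, names(tx_gene_map))
  if (length(unmapped))
    stop("transcript(s) without a gene mapping: ", paste(head(unmapped, 5), collapse = ", "))
  long <- as_tibble(as.matrix(tx_pseudobulk), rownames = "transcript_id") %>%
    tidyr::pivot_longer(-"transcript_id", names_to = "group", values_to = "count") %>%
    mutate(gene_id = unname(tx_gene_map[.data$transcript_id])) %>%
    group_by(.data$group, .data$gene_id) %>%
    mutate(gene_total = sum(.data$count)) %>%
    ungroup()
  absent <- long %>% filter(.data$gene_total == 0) %>%
    distinct(.data$group, .data$gene_id)
  out <- long %>% filter(.data$gene_total > 0) %>%
    mutate(fraction = .data$count / .data$gene_total) %>%
    select("group", "gene_id", "transcript_id", "count", "gene_total", "fraction") %>%
    arrange(.data$group, .data$gene_id, .data$transcript_id)
  attr(out, "absent") <- absent
  class(out) <- c("usage_fraction_table", class(out))
  out
}

#' Confusion matrix between two cell labelings
#'
#' Cross-tabulates two per-cell label vectors (e.g. cluster assignments
#' from gene-level and from transcript-level expression) over their common
#' barcodes. The grand total equals the number of shared cells; barcodes
#' exclusive to one labeling are reported in attributes.
#'
#' @param labels_a,labels_b named character vectors: barcode -> label.
#'   Rows of the result are `labels_a` classes, columns `labels_b` classes.
#' @return an integer matrix of class `confusion_matrix` with attributes
#'   `only_a` and `only_b` (exclusive barcode counts).
#' @export
confusion_matrix <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  if (length(common) == 0) stop("no barcode shared between the two labelings")
  cm <- unclass(table(a = labels_a[common], b = labels_b[common]))
  names(dimnames(cm)) <- NULL
  structure(cm, class = c("confusion_matrix", "matrix", "array"),
            only_a = length(labels_a) - length(common),
            only_b = length(labels_b) - length(common))
}

#' Row-normalised view of a confusion matrix
#' @param cm a [confusion_matrix()].
#' @return numeric matrix whose rows sum to 1 (all-zero rows stay 0).
#' @export
row_normalize <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, ifelse(rs == 0, 1, rs), "/")
  out
}

#' Concordance scores between two clusterings
#'
#' Maps each column class (method B, typically transcript-level clusters)
#' to a row class (method A, gene-level clusters) and scores how many of
#' the B class's cells land in its matched A class. `"argmax"` matching is
#' many-to-one: each B class takes the A class it shares most cells with
#' (ties resolved toward the larger A class, then lexicographically), so
#' two B subclusters of one A cluster can both score 100%.
#' `"hungarian"` computes the optimal one-to-one assignment
#' (via [clue::solve_LSAP()]); surplus B classes stay unmatched with `NA`
#' concordance. Overall concordance is matched cells / all shared cells.
#'
#' @param cm a [confusion_matrix()].
#' @param matching `"argmax"` (default) or `"hungarian"`.
#' @return tibble (`class_b`, `n`, `matched_a`, `concordance`) with
#'   attribute `overall` (fraction in `[0, 1]`).
#' @export
concordance_scores <- function(cm, matching = c("argmax", "hungarian")) {
  matching <- match.arg(matching)
  m <- unclass(cm)
  if (sum(m) == 0) stop("degenerate confusion matrix (no cells)")
  a_lab <- rownames(m); b_lab <- colnames(m)
  matched <- character(length(b_lab))
  if (matching == "argmax") {
    a_size <- rowSums(m)
    for (j in seq_along(b_lab)) {
      best <- which(m[, j] == max(m[, j]))
      if (length(best) > 1) {
        best <- best[a_size[best] == max(a_size[best])]
        if (length(best) > 1) best <- best[order(a_lab[best])][1]
      }
      matched[j] <- a_lab[best]
    }
  } else {
    k <- max(nrow(m), ncol(m))
    pad <- matrix(0, k, k)
    pad[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    sol <- as.integer(clue::solve_LSAP(pad, maximum = TRUE))
    matched <- rep(NA_character_, length(b_lab))
    for (i in seq_len(nrow(m))) {
      j <- sol[i]
      if (j <= ncol(m)) matched[j] <- a_lab[i]
    }
  }
  n_b <- colSums(m)
  shared <- vapply(seq_along(b_lab), function(j)
    if (is.na(matched[j])) NA_real_ else m[matched[j], j], numeric(1))
  out <- tibble(class_b = b_lab, n = as.integer(unname(n_b)),
                matched_a = matched,
                concordance = unname(shared / n_b))
  attr(out, "overall") <- sum(shared, na.rm = TRUE) / sum(m)
  out
}
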