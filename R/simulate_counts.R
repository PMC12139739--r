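#' Simulate paired gene/transcript count matrices with planted structure
#'
#' Draws a transcript-level cell x feature count matrix with known cluster
#' and replicate labels, and derives the gene-level matrix by summing each
#' gene's transcripts — so the two matrices aggregate exactly. Cluster
#' structure is planted through cluster-specific marker genes (elevated
#' expression); pure differential-transcript-usage signal is planted via
#' `effects`: for named genes, named clusters receive different transcript
#' proportions while the gene's expected total stays identical across
#' clusters (no gene-level signal).
#'
#' @param txome a [as_transcriptome()] object.
#' @param n_cells total number of cells.
#' @param n_clusters number of cell clusters (>= 2), labelled
#'   `"cluster1"`, ... Cells are split evenly.
#' @param replicates character vector of replicate names (>= 2); cells
#'   alternate between replicates within each cluster.
#' @param effects optional list of usage-shift specifications, each a list
#'   with `gene_id`, `cluster` and `props` (numeric over the gene's
#'   transcripts in transcript-id order, summing to 1). Clusters not named
#'   for a gene keep the baseline proportions.
#' @param counts_per_cell expected total counts per cell (Poisson mean,
#'   default 2000).
#' @param marker_fraction fraction of genes made cluster markers
#'   (default 0.1, 4-fold elevated in their cluster).
#' @param seed integer seed.
#' @return list with `tx` (transcripts x cells dgCMatrix), `gene` (genes x
#'   cells), `cells` (tibble: `barcode`, `cluster`, `replicate`), and
#'   `true_props` (tibble: `cluster`, `gene_id`, `transcript_id`, `prop`).
#' @export
simulate_count_matrices <- function(txome, n_cells, n_clusters,
                                    replicates = c("rep1", "rep2"),
                                    effects = NULL,
                                    counts_per_cell = 2000,
                                    marker_fraction = 0.1,
                                    seed = 1) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (length(replicates) < 2) stop("at least 2 replicates are required")
  map <- tx2gene(txome)
  txs <- sort(names(map))
  map <- map[txs]
  genes <- sort(unique(unname(map)))
  clusters <- sprintf("cluster%d", seq_len(n_clusters))
  effect_genes <- character(0)
  for (ef in effects) {
    if (!all(c("gene_id", "cluster", "props") %in% names(ef)))
      stop("each effect needs gene_id, cluster and props")
    if (!ef$gene_id %in% genes) stop("effect references unknown gene: ", ef$gene_id)
    if (!ef$cluster %in% clusters) stop("effect references unknown cluster: ", ef$cluster)
    k <- sum(map == ef$gene_id)
    if (length(ef$props) != k || any(ef$props < 0) || abs(sum(ef$props) - 1) > 1e-6)
      stop("effect props for ", ef$gene_id, " must be a simplex over its ", k, " transcripts")
    effect_genes <- c(effect_genes, ef$gene_id)
  }

  with_seed(seed, {
    # baseline gene expression (lognormal skew) and per-gene tx proportions
    lambda <- setNames(stats::rlnorm(length(genes), meanlog = 0, sdlog = 1), genes)
    base_props <- lapply(genes, function(g) {
      k <- sum(map == g)
      p <- rgamma(k, shape = 2)
      p / sum(p)
    })
    names(base_props) <- genes

    # cluster markers plant separable structure; DTU-effect genes excluded
    # so their gene-level expectation is equal across clusters
    candidates <- setdiff(genes, effect_genes)
    marker <- matrix(1, length(genes), n_clusters, dimnames = list(genes, clusters))
    n_mark <- if (marker_fraction > 0)
      max(1, round(marker_fraction * length(candidates))) else 0L
    for (cl in seq_len(n_clusters)) {
      if (n_mark == 0) break
      picks <- sample(candidates, min(n_mark, length(candidates)))
      marker[picks, cl] <- 4
    }

    cluster_of <- sort(rep(clusters, length.out = n_cells))
    replicate_of <- unlist(lapply(clusters, function(cl)
      rep(replicates, length.out = sum(cluster_of == cl))), use.names = FALSE)
    barcodes <- sprintf("CELL%05d", seq_len(n_cells))

    # per-cluster transcript weights: gene weight x within-gene proportions
    tx_weights <- sapply(clusters, function(cl) {
      props <- base_props
      for (ef in effects) if (ef$cluster == cl)
        props[[ef$gene_id]] <- ef$props
      w <- numeric(length(txs))
      for (gi in seq_along(genes)) {
        g <- genes[gi]
        idx <- which(map == g)
        w[idx] <- lambda[g] * marker[g, cl] * props[[g]]
      }
      w
    })

    sizes <- rpois(n_cells, counts_per_cell)
    tx_counts <- matrix(0L, length(txs), n_cells, dimnames = list(txs, barcodes))
    for (i in seq_len(n_cells)) {
      if (sizes[i] > 0)
        tx_counts[, i] <- stats::rmultinom(1, sizes[i], tx_weights[, cluster_of[i]])
    }
    tx_counts <- methods::as(Matrix::Matrix(tx_counts, sparse = TRUE), "CsparseMatrix")
    gene_counts <- aggregate_tx_to_gene(tx_counts, map)

    true_props <- bind_rows(lapply(clusters, function(cl) {
      props <- base_props
      for (ef in effects) if (ef$cluster == cl) props[[ef$gene_id]] <- ef$props
      bind_rows(lapply(genes, function(g)
        tibble(cluster = cl, gene_id = g,
               transcript_id = txs[map == g], prop = props[[g]])))
    }))

    list(tx = tx_counts, gene = gene_counts,
         cells = tibble(barcode = barcodes, cluster = cluster_of,
                        replicate = replicate_of),
         true_props = true_props)
  })
}

#' Sum a transcript-level matrix to gene level
#'
#' @param tx_counts transcripts x cells matrix with transcript row names.
#' @param tx_gene_map named character vector transcript -> gene.
#' @return genes x cells sparse matrix.
#' @export
aggregate_tx_to_gene <- function(tx_counts, tx_gene_map) {
  g <- tx_gene_map[rownames(tx_counts)]
  if (anyNA(g)) stop("unmapped transcripts in tx_counts")
  gf <- factor(unname(g))
  ind <- Matrix::sparseMatrix(i = as.integer(gf), j = seq_along(g), x = 1,
                              dims = c(nlevels(gf), length(g)))
  out <- methods::as(ind %*% tx_counts, "CsparseMatrix")
  rownames(out) <- levels(gf)
  colnames(out) <- colnames(tx_counts)
  out
}

#' Write a simulated experiment to disk
#'
#' Writes the transcript and gene matrices as MatrixMarket triplets with
#' `features.tsv` / `barcodes.tsv` sidecars (features x cells, the 10x
#' convention), plus the ground-truth cell labels as a TSV.
#'
#' @param sim output of [simulate_count_matrices()].
#' @param dir output directory (created if needed); writes `gene/` and
#'   `tx/` subdirectories and `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_count_matrices <- function(sim, dir) {
  for (what in c("gene", "tx")) {
    d <- file.path(dir, what)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    m <- sim[[what]]
    Matrix::writeMM(m, file.path(d, "matrix.mtx"))
    writeLines(rownames(m), file.path(d, "features.tsv"))
    writeLines(colnames(m), file.path(d, "barcodes.tsv"))
  }
  write.table(sim$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an MTX triplet directory
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (features x cells).
#' @return a sparse features x cells matrix with dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rn <- readLines(file.path(dir, "features.tsv"))
  cn <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(rn) || ncol(m) != length(cn))
    stop("matrix dimensions do not match features/barcodes files")
  dimnames(m) <- list(rn, cn)
  methods::as(m, "CsparseMatrix")
}

#' Read a two-column label TSV as a named vector
#'
#' @param path TSV with a header and two columns: barcode, label.
#' @return named character vector barcode -> label.
#' @export
read_labels <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("label file needs two columns (barcode, label)")
  if (anyDuplicated(d[[1]])) stop("duplicate barcodes in ", path)
  setNames(as.character(d[[2]]), d[[1]])
}
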