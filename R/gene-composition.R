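# Cross-sample gene presence/absence comparison.

#' Build a gene presence/absence matrix across samples
#'
#' A cell is \code{TRUE} when the gene is annotated at least once in that
#' sample (inverted-repeat duplicates collapse to one presence).
#'
#' @param records list of \code{\link{genome_record}} objects (>= 2).
#' @return logical matrix, samples in rows, normalized gene names in
#'   columns, both in first-appearance order.
#' @export
build_presence_matrix <- function(records) {
  if (length(records) < 2) stop("build_presence_matrix: need >= 2 records")
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("build_presence_matrix: duplicate sample IDs")
  gene_sets <- lapply(records, function(r) unique(r$genes$name))
  genes <- unique(unlist(gene_sets))
  m <- t(vapply(gene_sets, function(g) genes %in% g, logical(length(genes))))
  dimnames(m) <- list(ids, genes)
  if (any(rowSums(m) == 0))
    stop("build_presence_matrix: sample with no annotated genes")
  m
}

#' Genes unique to a focal sample set
#'
#' Genes present in every focal sample and absent from every other sample.
#'
#' @param matrix presence matrix from \code{\link{build_presence_matrix}}.
#' @param focal_samples character vector, a proper nonempty subset of the
#'   row names.
#' @return character vector of gene names.
#' @export
unique_genes <- function(matrix, focal_samples) {
  all_s <- rownames(matrix)
  if (!length(focal_samples) || !all(focal_samples %in% all_s))
    stop("unique_genes: focal_samples must be a nonempty subset of samples")
  rest <- setdiff(all_s, focal_samples)
  if (!length(rest))
    stop("unique_genes: focal_samples must not cover all samples")
  inside <- colSums(matrix[focal_samples, , drop = FALSE]) == length(focal_samples)
  outside <- colSums(matrix[rest, , drop = FALSE]) == 0
  colnames(matrix)[inside & outside]
}

#' Cluster samples by gene composition
#'
#' Average-linkage hierarchical clustering on the Jaccard distance between
#' presence/absence rows, with a flat two-cluster cut.
#'
#' @param matrix presence matrix.
#' @return list with \code{hclust} (the merge tree), \code{clusters}
#'   (named integer vector, the 2-cut; a single cluster when all rows are
#'   identical), \code{newick} (the dendrogram as a Newick string),
#'   \code{discriminating_genes} (genes whose presence differs between the
#'   two flat clusters) and \code{method} metadata.
#' @export
jaccard_cluster <- function(matrix) {
  if (nrow(matrix) < 2) stop("jaccard_cluster: need >= 2 samples")
  d <- vegan::vegdist(matrix * 1, method = "jaccard", binary = TRUE)
  d[is.na(d)] <- 0
  hc <- stats::hclust(d, method = "average")
  clusters <- if (max(d) == 0)
    stats::setNames(rep(1L, nrow(matrix)), rownames(matrix))
  else stats::cutree(hc, k = 2)
  disc <- character(0)
  if (max(clusters) == 2) {
    g1 <- colSums(matrix[clusters == 1, , drop = FALSE]) > 0
    g2 <- colSums(matrix[clusters == 2, , drop = FALSE]) > 0
    disc <- colnames(matrix)[xor(g1, g2)]
  }
  phy <- ape::as.phylo(hc)
  list(hclust = hc, clusters = clusters,
       newick = ape::write.tree(phy),
       discriminating_genes = disc,
       method = "average-linkage hierarchical clustering, binary Jaccard distance")
}
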