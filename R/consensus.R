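# Stability-selection consensus: re-infer the network on random sample
# subsets and keep edges recurring in at least m of k runs.

#' Consensus (stability-selection) configuration
#'
#' @param k number of subsample runs (default 6).
#' @param fraction fraction of samples per subset (default 0.5).
#' @param min_occurrence minimum number of runs an edge must appear in to
#'   be retained (default 5).
#' @param seed RNG seed for subsampling; per-subset seeds are derived as
#'   \code{seed + index}.
#' @return object of class \code{consensus_config}.
#' @export
consensus_config <- function(k = 6, fraction = 0.5, min_occurrence = 5,
                             seed = 1) {
  stopifnot(k >= 1, fraction > 0, fraction <= 1,
            min_occurrence >= 1, min_occurrence <= k)
  structure(list(k = as.integer(k), fraction = fraction,
                 min_occurrence = as.integer(min_occurrence),
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' Subsample the columns of an expression matrix
#'
#' Selects \code{floor(fraction * n_samples)} distinct columns uniformly
#' without replacement, reproducibly seeded by \code{(seed, index)};
#' selected columns keep their original order.
#'
#' @param matrix genes x samples matrix.
#' @param fraction fraction of columns to keep, in \code{(0, 1]}.
#' @param seed base seed.
#' @param index subset index (1-based).
#' @return the column-subset matrix.
#' @export
subsample_columns <- function(matrix, fraction, seed, index = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- ncol(matrix)
  m <- floor(fraction * n)
  if (m < 3) stop("subsample_columns: fewer than 3 samples would remain")
  cols <- sort(with_seed(seed + index, sample.int(n, m)))
  matrix[, cols, drop = FALSE]
}

#' Edge confidence from occurrence counts
#'
#' @param occurrence number of runs containing the edge.
#' @param k total number of runs.
#' @return percentage, \code{100 * occurrence / k}.
#' @examples
#' edge_confidence(5, 6)  # 83.33...
#' @export
edge_confidence <- function(occurrence, k) {
  stopifnot(all(occurrence >= 0), all(occurrence <= k))
  100 * occurrence / k
}

#' Infer a consensus network by subsample stability selection
#'
#' Runs \code{\link{infer_network}} on each of \code{k} random column
#' subsets, counts per-edge occurrence across runs, and retains edges with
#' occurrence at least \code{min_occurrence}.  Retained edges carry a
#' confidence (\code{100 * occurrence / k}) and the mean regression weight
#' over the runs containing them.  Per-subset engine seeds are derived as
#' \code{engine seed + index} so runs are independent but reproducible.
#'
#' @param matrix centered (and filtered) genes x samples matrix.
#' @param regulators regulator gene IDs.
#' @param engine an \code{\link{engine_config}}.
#' @param consensus a \code{\link{consensus_config}}.
#' @return object of class \code{c("consensus_grn", "grn_network")}; its
#'   \code{edges} gain \code{occurrence} and \code{confidence} columns, and
#'   \code{runs} holds the k per-subset networks' edge counts.
#' @export
consensus_network <- function(matrix, regulators,
                              engine = engine_config(),
                              consensus = consensus_config()) {
  k <- consensus$k
  nets <- vector("list", k)
  for (i in seq_len(k)) {
    sub <- subsample_columns(matrix, consensus$fraction, consensus$seed, i)
    eng_i <- engine
    eng_i$seed <- engine$seed + i
    nets[[i]] <- infer_network(sub, regulators, eng_i)
  }
  all_edges <- do.call(rbind, lapply(seq_len(k), function(i) {
    e <- nets[[i]]$edges
    if (nrow(e)) e$run <- i
    e
  }))
  if (is.null(all_edges) || !nrow(all_edges)) {
    edges <- data.frame(regulator = character(), target = character(),
                        weight = numeric(), occurrence = integer(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  } else {
    key <- paste(all_edges$regulator, all_edges$target, sep = "\r")
    occ <- tapply(all_edges$run, key, function(r) length(unique(r)))
    wt <- tapply(all_edges$weight, key, mean)
    keep <- names(occ)[occ >= consensus$min_occurrence]
    parts <- strsplit(keep, "\r", fixed = TRUE)
    edges <- data.frame(
      regulator = vapply(parts, `[`, character(1), 1),
      target = vapply(parts, `[`, character(1), 2),
      weight = unname(wt[keep]),
      occurrence = as.integer(unname(occ[keep])),
      stringsAsFactors = FALSE)
    edges$confidence <- edge_confidence(edges$occurrence, k)
    edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges,
                 modules = nets[[1]]$modules,
                 regulators = nets[[1]]$regulators,
                 config = engine, consensus = consensus,
                 n_samples = ncol(matrix),
                 runs = vapply(nets, function(n) nrow(n$edges), integer(1))),
            class = c("consensus_grn", "grn_network"))
}

#' @export
print.consensus_grn <- function(x, ...) {
  cat(sprintf(
    "<consensus_grn> %d consensus edges (>= %d of %d runs): %d regulators -> %d targets\n",
    nrow(x$edges), x$consensus$min_occurrence, x$consensus$k,
    length(unique(x$edges$regulator)), length(unique(x$edges$target))))
  invisible(x)
}
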