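# Network summary statistics and Fisher/FDR term enrichment.

edge_frame <- function(network) {
  if (inherits(network, "grn_network")) network$edges else
    as.data.frame(network, stringsAsFactors = FALSE)
}

#' Summarise a network
#'
#' @param network a \code{grn_network}/\code{consensus_grn} or an edge
#'   data.frame with \code{regulator} and \code{target} columns.
#' @return list with \code{n_regulators}, \code{n_targets}, \code{n_edges},
#'   \code{out_degree} (per regulator, decreasing) and \code{in_degree}
#'   (per target, decreasing).
#' @export
network_summary <- function(network) {
  e <- edge_frame(network)
  if (!nrow(e)) stop("network_summary: empty network")
  out_deg <- sort(table(e$regulator), decreasing = TRUE)
  in_deg <- sort(table(e$target), decreasing = TRUE)
  list(n_regulators = length(out_deg), n_targets = length(in_deg),
       n_edges = nrow(e), out_degree = out_deg, in_degree = in_deg)
}

#' Hub regulators by out-degree
#'
#' Regulators ranked by out-degree (number of targets), ties broken by
#' lexicographic ID.
#'
#' @param network see \code{\link{network_summary}}.
#' @param top_n number of hubs to return (default 10).
#' @return character vector of regulator IDs, highest degree first.
#' @export
hub_genes <- function(network, top_n = 10) {
  e <- edge_frame(network)
  if (!nrow(e)) stop("hub_genes: empty network")
  deg <- table(e$regulator)
  ord <- order(-as.numeric(deg), names(deg))
  utils::head(names(deg)[ord], top_n)
}

#' Fraction of edges regulated by each polymorphism group
#'
#' Each regulator may be associated with one or more location groups (via
#' its linked polymorphic chloroplast gene).  Per group this reports the
#' percentage of network edges whose regulator carries that label; edges
#' with multi-label regulators count once per label.  \code{any_group} is
#' the percentage of edges whose regulator carries at least one label, and
#' \code{any_group_targets} the analogous percentage of distinct targets.
#'
#' @param network see \code{\link{network_summary}}.
#' @param group_map data.frame with columns \code{regulator}, \code{group}
#'   (long format; one row per label).
#' @return list with \code{by_group} (named percentages),
#'   \code{any_group}, \code{any_group_targets} and \code{n_edges}.
#' @export
group_edge_fractions <- function(network, group_map) {
  e <- edge_frame(network)
  if (!nrow(e)) stop("group_edge_fractions: empty network")
  stopifnot(all(c("regulator", "group") %in% names(group_map)))
  labels <- split(group_map$group, group_map$regulator)
  groups <- sort(unique(group_map$group))
  by_group <- vapply(groups, function(g) {
    regs <- names(labels)[vapply(labels, function(l) g %in% l, logical(1))]
    100 * sum(e$regulator %in% regs) / nrow(e)
  }, numeric(1))
  labelled <- e$regulator %in% names(labels)
  list(by_group = by_group,
       any_group = 100 * sum(labelled) / nrow(e),
       any_group_targets = 100 * length(unique(e$target[labelled])) /
         length(unique(e$target)),
       n_edges = nrow(e))
}

#' Counts of all Venn regions over a collection of sets
#'
#' For n named sets, every element of the union is assigned to exactly one
#' of the 2^n - 1 exclusive membership regions.
#'
#' @param sets named list of character vectors.
#' @return data.frame with one indicator column per set plus \code{count};
#'   one row per membership pattern (all-absent row included with count 0
#'   semantics omitted).
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, paste, collapse = "")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(grid) <- names(sets)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    sum(pat == paste(unlist(grid[i, names(sets)]), collapse = ""))
  }, numeric(1))
  rownames(grid) <- NULL
  grid
}

# Two-sided Fisher exact p for one 2x2 table by the point-probability rule:
# sum of hypergeometric probabilities of all tables (with the observed
# margins) no more probable than the observed one.
fisher_p2 <- function(a, b, c, d) {
  k1 <- a + b          # target-set size
  K <- a + c           # term size
  N <- a + b + c + d
  x <- max(0, k1 + K - N):min(k1, K)
  probs <- stats::dhyper(x, K, N - K, k1)
  p_obs <- stats::dhyper(a, K, N - K, k1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input.
#'
#' @param p_values numeric vector of p-values in \code{[0, 1]}.
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of a target set by two-tailed Fisher tests
#'
#' For each term set, builds the 2x2 table of term membership for the
#' target set versus the rest of the background, computes a two-tailed
#' Fisher exact p-value (point-probability rule over the hypergeometric
#' distribution), and adjusts across all tested terms by
#' Benjamini-Hochberg.  Terms with no background overlap are skipped.
#'
#' @param target_set character vector, a subset of \code{background}.
#' @param background character vector of all genes.
#' @param term_sets named list of character vectors (e.g. read from GMT).
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame with columns \code{term}, \code{a}, \code{b},
#'   \code{c}, \code{d}, \code{p}, \code{q}, \code{significant}, ordered by
#'   increasing p; attribute \code{"skipped"} names terms with zero
#'   background overlap.
#' @export
fisher_enrichment <- function(target_set, background, term_sets,
                              alpha = 0.05) {
  target_set <- unique(target_set)
  background <- unique(background)
  if (!length(target_set)) stop("fisher_enrichment: empty target set")
  if (!all(target_set %in% background))
    stop("fisher_enrichment: target set not contained in background")
  rest <- setdiff(background, target_set)
  rows <- lapply(names(term_sets), function(tm) {
    members <- intersect(term_sets[[tm]], background)
    if (!length(members)) return(NULL)
    a <- sum(target_set %in% members)
    b <- length(target_set) - a
    cc <- sum(rest %in% members)
    d <- length(rest) - cc
    data.frame(term = tm, a = a, b = b, c = cc, d = d,
               p = fisher_p2(a, b, cc, d), stringsAsFactors = FALSE)
  })
  skipped <- names(term_sets)[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("fisher_enrichment: no term overlaps background")
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
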