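# Modular gene-regulatory-network inference.
#
# Per-target greedy forward selection of regulators under a Gaussian
# likelihood, with a module-consistency prior: targets are pre-clustered
# into co-expression modules, and a candidate regulator's score for a
# target is boosted in proportion to the fraction of the target's module
# co-members that already selected that regulator.  Iterating selection
# and module support couples the per-target regressions.

#' Engine configuration for network inference
#'
#' @param lambda sparsity penalty per added regulator, on the
#'   log-likelihood scale.  The default \code{NULL} uses the BIC
#'   per-parameter cost \code{log(n)/2} for n samples, which keeps the
#'   per-candidate false-selection rate shrinking with sample size; pass a
#'   number for a fixed penalty (2 is the AIC-scale cost).
#' @param beta module-prior strength (default 1); \code{beta = 0} reduces
#'   inference to independent per-target forward selection.
#' @param max_regulators maximum regulators selected per target (default 5).
#' @param n_iterations selection/support-recomputation sweeps (default 3).
#' @param h module-dendrogram cut height on correlation distance, in
#'   \code{(0, 2)} (default 0.6).
#' @param seed RNG seed, used only to break ties among equal score gains.
#' @param gain_cap finite ceiling for the score gain of a perfect fit.
#' @return object of class \code{engine_config}.
#' @export
engine_config <- function(lambda = NULL, beta = 1, max_regulators = 5,
                          n_iterations = 3, h = 0.6, seed = 1,
                          gain_cap = 1e6) {
  stopifnot(is.null(lambda) || lambda >= 0, beta >= 0, max_regulators >= 1,
            n_iterations >= 1, h > 0, h < 2)
  structure(list(lambda = lambda, beta = beta,
                 max_regulators = max_regulators,
                 n_iterations = n_iterations, h = h,
                 seed = as.integer(seed), gain_cap = gain_cap),
            class = "engine_config")
}

#' Zero-mean transform expression rows
#'
#' Subtracts each gene row's mean; required before filtering and inference.
#'
#' @param matrix numeric genes x samples matrix; no missing values.
#' @return centered matrix of the same shape.
#' @export
center_expression <- function(matrix) {
  if (anyNA(matrix)) stop("center_expression: missing values in matrix")
  sweep(matrix, 1, rowMeans(matrix))
}

#' Filter weakly varying genes
#'
#' Keeps genes whose centered expression deviates by at least
#' \code{min_abs} from the mean in at least \code{min_samples} samples.
#' Designated regulators are exempt from removal unless \code{strict}.
#'
#' @param matrix centered genes x samples matrix.
#' @param regulators character vector of regulator gene IDs (kept
#'   regardless of the threshold unless \code{strict = TRUE}).
#' @param min_abs deviation threshold (default 1).
#' @param min_samples minimum number of qualifying samples (default 5).
#' @param strict also filter regulators.
#' @return filtered matrix; attribute \code{"dropped"} lists removed genes.
#' @export
filter_expression <- function(matrix, regulators = character(),
                              min_abs = 1, min_samples = 5, strict = FALSE) {
  qualifies <- rowSums(abs(matrix) >= min_abs) >= min_samples
  keep <- qualifies | (!strict & rownames(matrix) %in% regulators)
  out <- matrix[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(matrix)[!keep]
  out
}

#' Assign target genes to co-expression modules
#'
#' Average-linkage hierarchical clustering of target rows on correlation
#' distance (1 - Pearson), cut at height \code{h}.  Constant rows have no
#' defined correlation and are placed in singleton modules with a warning.
#'
#' @param matrix centered targets x samples matrix (>= 2 rows).
#' @param h cut height in \code{(0, 2)}.
#' @return named integer vector, gene -> module id.
#' @export
init_modules <- function(matrix, h = 0.6) {
  if (nrow(matrix) < 2) stop("init_modules: need >= 2 target genes")
  sds <- apply(matrix, 1, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("init_modules: constant row(s) assigned to singleton modules: ",
            paste(utils::head(rownames(matrix)[const], 5), collapse = ", "))
  assign <- integer(nrow(matrix))
  names(assign) <- rownames(matrix)
  vary <- rownames(matrix)[!const]
  if (length(vary) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(matrix[vary, , drop = FALSE])))
    hc <- stats::hclust(d, method = "average")
    assign[vary] <- stats::cutree(hc, h = h)
  } else if (length(vary) == 1) assign[vary] <- 1L
  nmod <- max(assign, 0L)
  assign[const] <- nmod + seq_len(sum(const))
  assign
}

# Effective sparsity penalty: BIC per-parameter cost unless fixed.
effective_lambda <- function(config, n) {
  if (is.null(config$lambda)) log(n) / 2 else config$lambda
}

rss_of <- function(y, X) {
  if (is.null(X) || ncol(X) == 0) return(sum(y^2))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

#' Score gain of adding a candidate regulator
#'
#' Gaussian log-likelihood improvement minus the sparsity penalty plus the
#' module-prior bonus:
#' \code{gain = (n/2) * ln(RSS_current / RSS_with_candidate) - lambda +
#' beta * module_support}, with RSS from ordinary least squares of the
#' target on the predictor set (no intercept; rows are centered).  A
#' perfect fit is capped at \code{config$gain_cap}; a candidate collinear
#' with the current predictors is skipped (\code{NA}) with a warning.
#'
#' @param target_row centered target expression vector.
#' @param current_predictors matrix of currently selected regulator rows as
#'   columns (or \code{NULL}).
#' @param candidate_row centered candidate regulator vector.
#' @param module_support fraction of the target's module co-members that
#'   already selected this candidate (0 for singleton modules).
#' @param config an \code{\link{engine_config}}.
#' @return numeric score gain (\code{NA} when the candidate is collinear).
#' @export
score_edge <- function(target_row, current_predictors, candidate_row,
                       module_support = 0, config = engine_config()) {
  n <- length(target_row)
  rss_cur <- if (is.null(current_predictors) || ncol(current_predictors) == 0)
    sum(target_row^2)
  else rss_of(target_row, current_predictors)$rss
  X <- cbind(current_predictors, candidate_row)
  fit <- rss_of(target_row, X)
  if (fit$rank < ncol(X)) {
    warning("score_edge: candidate collinear with current predictors; skipped")
    return(NA_real_)
  }
  ll <- if (fit$rss <= 1e-10 * rss_cur || rss_cur <= 0) Inf else
    (n / 2) * log(rss_cur / fit$rss)
  min(ll, config$gain_cap) - effective_lambda(config, n) +
    config$beta * module_support
}

# One greedy forward-selection pass for a single target.
.select_regulators <- function(y, reg_mat, cand_order, support_fun, config) {
  chosen <- character(0)
  rss_cur <- sum(y^2)
  lam <- effective_lambda(config, length(y))
  X <- NULL
  while (length(chosen) < config$max_regulators) {
    cands <- setdiff(cand_order, chosen)
    if (!length(cands)) break
    gains <- rep(NA_real_, length(cands))
    rsses <- rep(NA_real_, length(cands))
    for (i in seq_along(cands)) {
      Xc <- cbind(X, reg_mat[, cands[i]])
      fit <- suppressWarnings(rss_of(y, Xc))
      if (fit$rank < ncol(Xc)) next
      ll <- if (fit$rss <= 1e-10 * rss_cur || rss_cur <= 0) config$gain_cap
      else min((length(y) / 2) * log(rss_cur / fit$rss), config$gain_cap)
      gains[i] <- ll - lam + config$beta * support_fun(cands[i])
      rsses[i] <- fit$rss
    }
    if (all(is.na(gains)) || max(gains, na.rm = TRUE) <= 0) break
    best <- which.max(gains)            # first index wins ties: seeded order
    chosen <- c(chosen, cands[best])
    X <- cbind(X, reg_mat[, cands[best]])
    rss_cur <- rsses[best]
  }
  chosen
}

#' Infer a regulator-to-target network
#'
#' Targets are clustered into modules once; then, for \code{n_iterations}
#' sweeps, each target independently runs greedy forward selection over the
#' regulators (adding the regulator with the maximal positive score gain,
#' see \code{\link{score_edge}}) and module support is recomputed from the
#' resulting edge set.  Self-edges are forbidden.  Deterministic given the
#' config seed, which only shuffles the candidate order used to break ties
#' between equal gains (lexicographic regulator ID underneath).
#'
#' @param matrix centered (and typically filtered) genes x samples matrix.
#' @param regulators character vector of regulator gene IDs present in the
#'   matrix; all other rows are targets.
#' @param config an \code{\link{engine_config}}.
#' @return object of class \code{grn_network}: list with \code{edges}
#'   (data.frame \code{regulator}, \code{target}, \code{weight}),
#'   \code{modules}, \code{regulators}, \code{config}, \code{n_samples}.
#' @export
infer_network <- function(matrix, regulators, config = engine_config()) {
  regulators <- intersect(rownames(matrix), regulators)
  if (!length(regulators)) stop("infer_network: no regulators in matrix")
  targets <- setdiff(rownames(matrix), regulators)
  if (!length(targets)) stop("infer_network: no target genes in matrix")
  reg_mat <- t(matrix[regulators, , drop = FALSE])
  colnames(reg_mat) <- regulators

  modules <- if (length(targets) >= 2)
    suppressWarnings(init_modules(matrix[targets, , drop = FALSE], config$h))
  else stats::setNames(1L, targets)
  comembers <- lapply(stats::setNames(targets, targets), function(tg)
    setdiff(names(modules)[modules == modules[tg]], tg))

  cand_order <- with_seed(config$seed, sample(sort(regulators)))
  sel <- stats::setNames(vector("list", length(targets)), targets)
  for (iter in seq_len(config$n_iterations)) {
    prev <- sel
    sel <- lapply(stats::setNames(targets, targets), function(tg) {
      cm <- comembers[[tg]]
      support_fun <- if (!length(cm)) function(r) 0 else function(r)
        mean(vapply(prev[cm], function(s) r %in% s, logical(1)))
      cands <- setdiff(cand_order, tg)   # no self-edges
      .select_regulators(matrix[tg, ], reg_mat, cands, support_fun, config)
    })
    if (identical(sel, prev)) break
  }

  edges <- do.call(rbind, lapply(targets, function(tg) {
    regs <- sel[[tg]]
    if (!length(regs)) return(NULL)
    fit <- stats::lm.fit(reg_mat[, regs, drop = FALSE], matrix[tg, ])
    data.frame(regulator = regs, target = tg,
               weight = unname(fit$coefficients[seq_along(regs)]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(regulator = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges, modules = modules, regulators = regulators,
                 config = config, n_samples = ncol(matrix)),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf(
    "<grn_network> %d edges: %d regulators -> %d targets (%d samples)\n",
    nrow(x$edges), length(unique(x$edges$regulator)),
    length(unique(x$edges$target)), x$n_samples))
  invisible(x)
}

#' @export
summary.grn_network <- function(object, ...) {
  s <- network_summary(object)
  cat(sprintf("Regulator-target network inferred from %d samples\n",
              object$n_samples))
  cat(sprintf("  edges: %d | regulators: %d | targets: %d\n",
              s$n_edges, s$n_regulators, s$n_targets))
  cat(sprintf("  modules: %d | lambda = %s, beta = %g, max %d regulators/target\n",
              length(unique(object$modules)),
              if (is.null(object$config$lambda)) "BIC (log(n)/2)" else
                format(object$config$lambda),
              object$config$beta, object$config$max_regulators))
  if (s$n_edges) {
    cat("  top out-degrees:\n")
    print(utils::head(s$out_degree, 5))
  }
  invisible(s)
}

#' @export
coef.grn_network <- function(object, ...) {
  stats::setNames(object$edges$weight,
                  paste(object$edges$regulator, object$edges$target, sep = "->"))
}

#' @export
plot.grn_network <- function(x, ...) {
  s <- network_summary(x)
  graphics::barplot(s$out_degree, las = 2, cex.names = 0.7,
                    ylab = "out-degree",
                    main = "Regulator out-degree distribution", ...)
  invisible(x)
}
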