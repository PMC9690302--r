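# Independent forward-selection oracle built on normal equations only;
# mirrors none of the package's fitting code paths.
oracle_rss <- function(y, X) {
  if (is.null(X) || ncol(X) == 0) return(sum(y^2))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

oracle_forward_selection <- function(y, reg_mat, lambda, max_k) {
  chosen <- character(0)
  repeat {
    if (length(chosen) >= max_k) break
    cands <- setdiff(colnames(reg_mat), chosen)
    if (!length(cands)) break
    rss0 <- oracle_rss(y, reg_mat[, chosen, drop = FALSE])
    gains <- vapply(cands, function(cd) {
      rss1 <- oracle_rss(y, reg_mat[, c(chosen, cd), drop = FALSE])
      (length(y) / 2) * log(rss0 / rss1) - lambda
    }, numeric(1))
    if (max(gains) <= 0) break
    chosen <- c(chosen, cands[which.max(gains)])
  }
  chosen
}

test_that("centering removes row means and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  cm <- center_expression(m)
  expect_equal(unname(cm["a", ]), c(-1, 0, 1))
  expect_equal(center_expression(cm), cm)
  r <- with_seed2(3, matrix(rnorm(50 * 20), 50))
  expect_lt(max(abs(rowMeans(center_expression(r)))), 1e-9)
  expect_error(center_expression(rbind(c(1, NA))), "missing")
})

test_that("expression filter keeps deviating genes and exempts regulators", {
  m <- rbind(keep = c(rep(1.0, 5), rep(0, 7)),   # exactly 5 of 12 qualify
             zero = rep(0, 12))
  out <- filter_expression(m)
  expect_true("keep" %in% rownames(out))
  expect_false("zero" %in% rownames(out))
  expect_equal(attr(out, "dropped"), "zero")
  # regulators survive unless strict
  m2 <- rbind(reg = rep(0, 12), m)
  expect_true("reg" %in% rownames(filter_expression(m2, regulators = "reg")))
  expect_false("reg" %in%
                 rownames(filter_expression(m2, regulators = "reg",
                                            strict = TRUE)))
  # counting oracle on a random matrix
  r <- with_seed2(11, matrix(rnorm(200 * 12, sd = 0.8), 200,
                             dimnames = list(sprintf("g%03d", 1:200), NULL)))
  kept <- rownames(filter_expression(r))
  oracle <- rownames(r)[vapply(seq_len(nrow(r)), function(i)
    sum(abs(r[i, ]) >= 1) >= 5, logical(1))]
  expect_equal(kept, oracle)
})

test_that("module initialisation recovers block structure", {
  base1 <- with_seed2(4, rnorm(30)); base2 <- with_seed2(5, rnorm(30))
  m <- rbind(a1 = base1, a2 = base1, b1 = base2, b2 = base2)
  mod <- suppressWarnings(init_modules(m))
  expect_equal(mod[["a1"]], mod[["a2"]])
  expect_equal(mod[["b1"]], mod[["b2"]])
  expect_false(mod[["a1"]] == mod[["b1"]])
  # near-maximal cut height collapses everything into one module
  expect_length(unique(init_modules(m, h = 1.999)), 1)
  # planted modules recovered at the default cut
  sim <- simulate_expression()
  mod <- init_modules(center_expression(sim$matrix)[names(sim$truth_modules), ])
  expect_gte(ari(mod, sim$truth_modules), 0.9)
  # constant rows fall into singleton modules with a warning
  expect_warning(init_modules(rbind(x = base1, y = base1, z = rep(1, 30))),
                 "constant")
})

test_that("edge score gain matches its closed form and the normal-equation oracle", {
  cfg1 <- engine_config(lambda = 1, beta = 0)
  y <- c(1, -1, 1, -1)
  orth <- c(1, 1, -1, -1)                        # exactly orthogonal to y
  expect_equal(score_edge(y, NULL, orth, 0, cfg1), -1)
  # a perfect predictor caps at the ceiling
  expect_equal(score_edge(y, NULL, y, 0, cfg1),
               cfg1$gain_cap - 1)
  # random instances against the oracle
  with_seed2(21, {
    for (i in 1:25) {
      n <- 20
      X0 <- matrix(rnorm(n * 2), n)
      cand <- rnorm(n)
      yy <- rnorm(n)
      gain <- score_edge(yy, X0, cand, module_support = 0.5,
                         config = engine_config(lambda = 2, beta = 1.5))
      oracle <- (n / 2) * log(oracle_rss(yy, X0) /
                                oracle_rss(yy, cbind(X0, cand))) -
        2 + 1.5 * 0.5
      expect_equal(gain, oracle, tolerance = 1e-6)
    }
  })
  # collinear candidates are skipped with a warning
  X <- cbind(c(1, 2, 3, 4))
  expect_warning(g <- score_edge(y, X, c(2, 4, 6, 8), 0, cfg1), "collinear")
  expect_true(is.na(g))
})

test_that("a dominant regulator is the sole selected parent", {
  with_seed2(55, {
    n <- 100
    regs <- matrix(rnorm(4 * n), 4, dimnames = list(paste0("R", 1:4), NULL))
    y <- 0.9 * regs["R1", ] + rnorm(n, sd = 0.01)
    m <- rbind(regs, tgt = y)
    net <- infer_network(center_expression(m), paste0("R", 1:4))
    expect_equal(nrow(net$edges), 1)
    expect_equal(net$edges$regulator, "R1")
    expect_equal(net$edges$target, "tgt")
    expect_equal(net$edges$weight, 0.9, tolerance = 0.01)
  })
})

test_that("pure-noise targets yield an empty network at a strong penalty", {
  with_seed2(70, {
    n <- 60
    m <- matrix(rnorm(8 * n), 8,
                dimnames = list(c(paste0("R", 1:3), paste0("T", 1:5)), NULL))
    net <- infer_network(center_expression(m), paste0("R", 1:3),
                         engine_config(lambda = 4, seed = 1))
    expect_equal(nrow(net$edges), 0)
  })
})

test_that("beta = 0 reduces inference to independent forward selection", {
  sim <- simulate_expression(synth_expr_config(
    n_regulators = 6, n_modules = 3, targets_per_module = 8,
    n_samples = 80, noise_sd = 0.5, seed = 12))
  X <- center_expression(sim$matrix)
  lam <- 3
  net <- infer_network(X, sim$regulators,
                       engine_config(lambda = lam, beta = 0, seed = 9))
  reg_mat <- t(X[sim$regulators, ])
  oracle_edges <- unlist(lapply(names(sim$truth_modules), function(tg) {
    paste(oracle_forward_selection(X[tg, ], reg_mat, lam, 5), tg)
  }))
  expect_setequal(edge_keys(net), oracle_edges)
})

test_that("edge sets are invariant under sample-column permutation", {
  sim <- simulate_expression(synth_expr_config(
    n_regulators = 4, n_modules = 2, targets_per_module = 6,
    n_samples = 60, seed = 3))
  X <- center_expression(sim$matrix)
  net1 <- infer_network(X, sim$regulators, engine_config(seed = 5))
  perm <- with_seed2(2, sample(ncol(X)))
  net2 <- infer_network(X[, perm], sim$regulators, engine_config(seed = 5))
  expect_setequal(edge_keys(net1), edge_keys(net2))
})

test_that("increasing the sparsity penalty never grows the edge set", {
  sim <- simulate_expression(synth_expr_config(
    n_regulators = 6, n_modules = 3, targets_per_module = 8,
    n_samples = 80, noise_sd = 0.6, seed = 8))
  X <- center_expression(sim$matrix)
  sizes <- vapply(c(0.5, 1, 2, 4, 8), function(lam)
    nrow(infer_network(X, sim$regulators,
                       engine_config(lambda = lam, beta = 0,
                                     seed = 4))$edges), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted modular structure is recovered with high precision and recall", {
  sim <- simulate_expression(synth_expr_config(
    n_regulators = 6, n_modules = 3, targets_per_module = 10,
    n_samples = 120, seed = 42))
  X <- center_expression(sim$matrix)
  net <- infer_network(X, sim$regulators, engine_config(seed = 42))
  truth <- paste(sim$truth_edges$regulator, sim$truth_edges$target)
  found <- edge_keys(net)
  expect_gte(mean(truth %in% found), 0.9)   # recall
  expect_gte(mean(found %in% truth), 0.9)   # precision
  # model-object surface
  expect_output(print(net), "grn_network")
  expect_named(coef(net))
  s <- network_summary(net)
  expect_equal(s$n_regulators, 6)
})

test_that("inference rejects degenerate inputs", {
  m <- matrix(rnorm(20), 4, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(infer_network(m, character()), "no regulators")
  expect_error(infer_network(m, rownames(m)), "no target")
})
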