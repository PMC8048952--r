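star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr
}

test_that("mortality rule classifies strategy with an unknown middle band", {
  expect_equal(classify_strategy(c(25, 80, 50)), c(1L, 0L, NA))
  expect_equal(classify_strategy(c(0, 100, 30, 70)), c(1L, 0L, NA, NA))
  expect_error(classify_strategy(120), "percentage")
  expect_error(classify_strategy(-5), "percentage")
})

test_that("phylogenetic logistic regression reduces to Firth logistic on a star tree", {
  withr::with_seed(41, {
    n <- 80
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + x))
  })
  tr <- star_tree(n)
  d <- data.frame(species = tr$tip.label, strategy = y, x = x)
  fit <- phylo_logistic_mple(strategy ~ x, d, tr)
  ora <- firth_logistic_oracle(cbind(1, x), y)
  expect_lt(max(abs(fit$coefficients - ora)), 1e-4)
  expect_true(fit$converged)
})

test_that("the phylogenetic model collapses to Firth logistic as the signal vanishes", {
  # on a structured tree, forcing a huge reversion rate must reproduce the
  # independent penalized fit
  tr <- simulate_phylogeny(70, seed = 3)
  withr::with_seed(42, {
    x <- rnorm(70)
    y <- rbinom(70, 1, plogis(0.5 * x))
  })
  d <- data.frame(species = tr$tip.label, strategy = y, x = x)
  fit <- phylo_logistic_mple(strategy ~ x, d, tr, alpha_bounds = c(5e4, 1e5))
  ora <- firth_logistic_oracle(cbind(1, x), y)
  expect_lt(max(abs(fit$coefficients - ora)), 1e-4)
})

test_that("coefficients survive separation and are finite", {
  tr <- simulate_phylogeny(40, seed = 9)
  x <- sort(rnorm(40))
  y <- as.integer(seq_len(40) > 20)   # complete separation in x
  d <- data.frame(species = tr$tip.label, strategy = y, x = x)
  fit <- phylo_logistic_mple(strategy ~ x, d, tr)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(abs(fit$coefficients["x"]), 50)
})

test_that("coefficient estimates are invariant to tip-order permutation", {
  tr <- simulate_phylogeny(50, seed = 21)
  withr::with_seed(22, {
    x <- rnorm(50)
    y <- simulate_binary_trait(tr, cbind(x), c(0, 1), alpha = 2)
  })
  d <- data.frame(species = tr$tip.label, strategy = as.integer(y), x = x)
  f1 <- phylo_logistic_mple(strategy ~ x, d, tr)
  perm <- withr::with_seed(5, sample(nrow(d)))
  f2 <- phylo_logistic_mple(strategy ~ x, d[perm, ], tr)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-4)
})

test_that("degenerate designs and name mismatches raise clear errors", {
  tr <- simulate_phylogeny(30, seed = 2)
  d <- data.frame(species = tr$tip.label, strategy = rep(c(0, 1), 15), x = 1)
  expect_error(phylo_logistic_mple(strategy ~ x, d, tr), "constant predictor")
  d2 <- data.frame(species = c(tr$tip.label[-1], "not_a_tip"),
                   strategy = rep(c(0, 1), 15), x = rnorm(30))
  expect_error(phylo_logistic_mple(strategy ~ x, d2, tr), "absent from the tree")
  d3 <- d; d3$x <- rnorm(30); d3$strategy <- d3$strategy + 1
  expect_error(phylo_logistic_mple(strategy ~ x, d3, tr), "0/1")
})

test_that("the strategy-model slope is recovered across replicate trees", {
  ests <- withr::with_seed(77, {
    vapply(1:25, function(i) {
      tr <- simulate_phylogeny(120)
      x <- rnorm(120)
      y <- simulate_binary_trait(tr, cbind(x), c(0, 1), alpha = 2)
      d <- data.frame(species = tr$tip.label, strategy = as.integer(y), x = x)
      unname(phylo_logistic_mple(strategy ~ x, d, tr)$coefficients["x"])
    }, numeric(1))
  })
  expect_lt(abs(mean(ests) - 1), 0.15)
  expect_true(all(ests > 0))
})

test_that("parametric bootstrap intervals are seed-reproducible and bracket estimates", {
  tr <- simulate_phylogeny(60, seed = 13)
  withr::with_seed(14, {
    x <- rnorm(60)
    y <- simulate_binary_trait(tr, cbind(x), c(0.3, 0.9), alpha = 2)
  })
  d <- data.frame(species = tr$tip.label, strategy = as.integer(y), x = x)
  fit <- phylo_logistic_mple(strategy ~ x, d, tr)
  b1 <- bootstrap_ci(fit, n_boot = 150, seed = 99)
  b2 <- bootstrap_ci(fit, n_boot = 150, seed = 99)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$ci_upper, b2$ci_upper)
  expect_true(all(b1$ci_lower <= fit$coefficients + 1e-8))
  expect_true(all(b1$ci_upper >= fit$coefficients - 1e-8))
  expect_error(bootstrap_ci(fit, n_boot = 10), "n_boot")
})

test_that("PGLS equals OLS on a star tree and a matrix-algebra oracle on any tree", {
  n <- 40
  st <- star_tree(n)
  withr::with_seed(31, { x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n) })
  d <- data.frame(species = st$tip.label, x = x, y = y)
  fit <- pgls_fit(y ~ x, d, st)
  ols <- lm(y ~ x)
  expect_lt(max(abs(fit$coefficients - coef(ols))), 1e-10)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(fit$Fstat, unname(summary(ols)$fstatistic[1]), tolerance = 1e-8)
  # exact linear relation
  d2 <- data.frame(species = st$tip.label, x = x, y = 2 * x)
  fit2 <- pgls_fit(y ~ x, d2, st)
  expect_equal(fit2$slope, 2, tolerance = 1e-10)
  expect_equal(fit2$r2, 1, tolerance = 1e-10)
  # Brownian-simulated data on a structured tree vs direct GLS algebra
  tr <- simulate_phylogeny(50, seed = 8)
  withr::with_seed(9, {
    xb <- ape::rTraitCont(tr)
    yb <- 0.7 * xb + ape::rTraitCont(tr)
  })
  db <- data.frame(species = tr$tip.label, x = xb, y = yb)
  fitb <- pgls_fit(y ~ x, db, tr)
  C <- ape::vcv(tr)
  ora <- gls_oracle(cbind(1, xb), yb, C)
  expect_lt(max(abs(fitb$coefficients - ora)), 1e-8)
})

test_that("leaf-trait PCA fixes signs, centers scores, and conserves variance", {
  withr::with_seed(55, {
    n <- 40
    leaf_n <- rnorm(n, 20, 4)
    cn <- 800 / leaf_n + rnorm(n, 0, 1)     # strongly negative with leaf N
    sla <- rnorm(n, 15, 3)
  })
  tr <- data.frame(species = sprintf("s%02d", 1:n), sla = sla,
                   leaf_n = leaf_n, cn_ratio = cn)
  pca <- leaf_trait_pca(tr)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-12)
  expect_gt(pca$loadings["leaf_n", 1], 0)
  expect_gt(pca$loadings["sla", 2], 0)
  expect_equal(mean(pca$scores$dim1), 0, tolerance = 1e-12)
  expect_equal(mean(pca$scores$dim2), 0, tolerance = 1e-12)
  # dim1 carries the N / C:N axis when they are collinear
  expect_gt(cor(pca$scores$dim1, leaf_n), 0.9)
  expect_lt(cor(pca$scores$dim1, cn), -0.9)
  # three orthogonal unit-variance traits share variance equally
  d3 <- data.frame(species = c("a", "b", "c", "d"),
                   sla = c(1, 1, -1, -1), leaf_n = c(1, -1, 1, -1),
                   cn_ratio = c(1, -1, -1, 1))
  p3 <- leaf_trait_pca(d3)
  expect_equal(unname(p3$variance_fraction), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(leaf_trait_pca(transform(tr, sla = 1)), "constant")
})
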