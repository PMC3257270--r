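test_that("pseudocount aggregation conserves mass on every tree", {
  set.seed(1)
  ## complete tree: per-leaf vector equals the context's own row
  alpha <- matrix(runif(27, .1, 2), 9, 3)
  comp <- build_complete_tree(3, 2)
  agg <- aggregate_pseudocounts(alpha, comp)
  expect_equal(unname(agg[comp$context_map, ]), unname(alpha))
  ## fused tree with unit pseudocounts: 3^2 contexts x 1 each
  fused <- build_fused_tree(3, 2)
  expect_equal(unname(aggregate_pseudocounts(matrix(1, 9, 3), fused)),
               matrix(9, 1, 3))
  ## random parsimonious tree: totals conserved
  st <- select_optimal_tree(matrix(rgamma(27, 1), 9), alpha, -1, 3, 2)
  agg2 <- aggregate_pseudocounts(alpha, st$tree)
  expect_equal(sum(agg2), sum(alpha))
  expect_error(aggregate_pseudocounts(alpha[1:8, ], comp), "all K\\^k")
})

test_that("tree-structure prior is linear in the leaf count", {
  comp <- build_complete_tree(3, 2)
  fused <- build_fused_tree(3, 2)
  expect_equal(log_tree_structure_prior(comp, 0), 0)
  expect_equal(log_tree_structure_prior(fused, 0), 0)
  ## one-leaf difference = kappa, by linearity
  expect_equal(log_tree_structure_prior(comp, 2.5) -
                 log_tree_structure_prior(build_complete_tree(3, 2), 2.5), 0)
  ## kappa = -5: fused vs complete differ by -5 * (1 - 9) = 40
  expect_equal(log_tree_structure_prior(fused, -5) -
                 log_tree_structure_prior(comp, -5), 40)
})

test_that("transformed-Dirichlet transition prior has the closed form", {
  ## single-leaf tree, K = 2, a = (1,1), p = (.5,.5):
  ## 2 log .5 - log(G(1)G(1)/G(2)) = -2 log 2
  tree <- build_fused_tree(2, 1, states = c("a", "b"))
  tm <- transition_matrix(tree, matrix(c(.5, .5), 1))
  hy <- hyperparameters(initial = c(1, 1),
                        transition = list(matrix(1 / 2, 2, 2)),
                        kappa = 0,
                        emission = list(m = c(0, 0), tau = c(1, 1),
                                        a = c(2, 2), b = c(1, 1)))
  ## aggregated leaf pseudocounts: (1/2 + 1/2, 1/2 + 1/2) = (1, 1)
  expect_equal(log_transition_prior(list(tm), hy), -2 * log(2),
               tolerance = 1e-12)
})

test_that("complete-tree prior equals independent per-context terms", {
  set.seed(2)
  K <- 3L
  alpha <- matrix(runif(27, .2, 1.5), 9, K)
  tm <- random_complete_tm(K, 2L)
  hy <- hyperparameters(initial = rep(1, K), transition = list(
    matrix(1 / K, K, K), alpha), kappa = 0.7,
    emission = list(m = rep(0, K), tau = rep(1, K), a = rep(2, K),
                    b = rep(1, K)))
  ## independent sum over contexts (complete tree: leaf = context)
  P <- context_probs(tm)
  manual <- 0
  for (cc in 1:9) {
    a <- alpha[cc, ]
    manual <- manual + sum(a * log(P[cc, ])) -
      (sum(lgamma(a)) - lgamma(sum(a)))
  }
  manual <- manual + 0.7 * 9
  hy1 <- hy; hy1$transition <- list(alpha)
  expect_equal(log_transition_prior(list(tm), hy1), manual, tolerance = 1e-9)
})

test_that("the prior mode of a leaf is the normalized pseudocounts", {
  ## Lagrange condition for sum_j a_j log p_j: maximizer p = a / sum(a)
  a <- c(2, 5, 1)
  ls <- leaf_score(c(0, 0, 0), a)
  expect_equal(ls$probs, a / sum(a))
  ## perturbations score lower
  for (eps in c(.01, .1)) {
    p2 <- ls$probs + c(eps, -eps, 0)
    expect_lt(sum(a * log(p2)), sum(a * log(ls$probs)))
  }
})

test_that("log_prior is additive and finite on prior-sampled models", {
  set.seed(3)
  values <- rnorm(500)
  hy <- default_hyperparameters(values, 3L, order = 2L)
  for (i in 1:20) {
    drawn <- sample_from_prior(hy, 3L, 2L)
    m <- phhmm(order = 2, initial = drawn$initial,
               transitions = drawn$transitions,
               mean = c(-1.5, 0, 1.5), sd = c(.5, .3, .5))
    lp <- log_prior(m, hy)
    expect_true(is.finite(lp))
    ## additivity of the three components
    manual <- sum(hy$initial * log(drawn$initial)) -
      (sum(lgamma(hy$initial)) - lgamma(sum(hy$initial))) +
      log_transition_prior(m$transitions, hy)
    em <- hy$emission
    for (s in 1:3) {
      s2 <- m$emissions$sd[s]^2
      manual <- manual + em$a[s] * log(em$b[s]) - lgamma(em$a[s]) -
        (em$a[s] + 1) * log(s2) - em$b[s] / s2 +
        0.5 * (log(em$tau[s]) - log(2 * pi) - log(s2)) -
        em$tau[s] * (m$emissions$mean[s] - em$m[s])^2 / (2 * s2)
    }
    expect_equal(lp, unname(manual), tolerance = 1e-9)
  }
})

test_that("order-0 models have no transition prior term", {
  values <- rnorm(100)
  hy <- default_hyperparameters(values, 3L, order = 1L)
  m0 <- phhmm(order = 0, initial = c(.2, .6, .2), transitions = list(),
              mean = c(-1, 0, 1), sd = c(1, 1, 1))
  m1 <- phhmm(order = 1, initial = c(.2, .6, .2),
              transitions = list(random_complete_tm(3L, 1L)),
              mean = c(-1, 0, 1), sd = c(1, 1, 1))
  expect_equal(log_prior(m1, hy) - log_prior(m0, hy),
               log_transition_prior(m1$transitions, hy), tolerance = 1e-9)
})

test_that("prior sampling is reproducible and moment-correct", {
  hy <- hyperparameters(initial = c(2, 5, 3),
                        transition = list(matrix(c(4, 1, 1,
                                                   1, 4, 1,
                                                   1, 1, 4), 3, byrow = TRUE)),
                        kappa = 0,
                        emission = list(m = rep(0, 3), tau = rep(1, 3),
                                        a = rep(2, 3), b = rep(1, 3)))
  d1 <- sample_from_prior(hy, 3L, 1L, seed = 42)
  d2 <- sample_from_prior(hy, 3L, 1L, seed = 42)
  expect_identical(d1, d2)
  expect_equal(sum(d1$initial), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(d1$transitions[[1L]]$probs)), rep(1, 3),
               tolerance = 1e-12)
  ## Dirichlet moments: mean of row 1 over many draws ~ alpha / sum(alpha)
  set.seed(1)
  draws <- vapply(1:10000, function(i) {
    sample_from_prior(hy, 3L, 1L)$transitions[[1L]]$probs[1L, ]
  }, numeric(3))
  a <- c(4, 1, 1); a0 <- sum(a)
  mom <- a / a0
  se <- sqrt(mom * (1 - mom) / (a0 + 1)) / sqrt(10000)
  expect_true(all(abs(rowMeans(draws) - mom) < 3 * se))
})

test_that("boundary probabilities against positive pseudocounts give -Inf", {
  tree <- build_fused_tree(2, 1, states = c("a", "b"))
  tm <- transition_matrix(tree, matrix(c(1, 0), 1))
  hy <- hyperparameters(initial = c(1, 1),
                        transition = list(matrix(0.5, 2, 2)), kappa = 0,
                        emission = list(m = c(0, 0), tau = c(1, 1),
                                        a = c(2, 2), b = c(1, 1)))
  expect_identical(log_transition_prior(list(tm), hy), -Inf)
})
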