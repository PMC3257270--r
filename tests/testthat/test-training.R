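make_hyper <- function(values, order, kappa = 0) {
  default_hyperparameters(values, 3L, order = max(order, 1L), kappa = kappa)
}

test_that("initial-distribution MAP update is pseudocount-smoothed", {
  hy <- list(initial = c(1, 1, 1))
  expect_equal(m_step_initial(c(1, 0, 0), hy), c(1 / 2, 1 / 4, 1 / 4))
  expect_equal(m_step_initial(c(0, 0, 0), hy), rep(1 / 3, 3))
  expect_equal(sum(m_step_initial(rgamma(3, 2), list(initial = c(2, 1, 3)))), 1)
})

test_that("emission MAP updates obey the conjugate limits", {
  set.seed(1)
  o <- rnorm(200, 1, 2)
  prof <- list(cgh_profile("c", (0:199) * 350, (0:199) * 350 + 60, o))
  g <- matrix(0, 200, 3); g[, 2L] <- 1
  ## tau -> Inf: posterior mean pinned at the prior location
  hy_strong <- list(emission = list(m = c(-1, 5, 1), tau = rep(1e12, 3),
                                    a = rep(2, 3), b = rep(1, 3)))
  expect_equal(m_step_emissions(prof, list(g), hy_strong)$mean[2L], 5,
               tolerance = 1e-6)
  ## tau = 0, a, b -> 0: maximum-likelihood limit for the occupied state
  hy_ml <- list(emission = list(m = rep(0, 3), tau = rep(0, 3),
                                a = rep(1e-12, 3), b = rep(1e-12, 3)))
  ml <- m_step_emissions(prof, list(g), hy_ml)
  expect_equal(ml$mean[2L], mean(o), tolerance = 1e-9)
  ## joint-mode denominator 2a + 3 + n -> n + 3 in the a,b -> 0 limit
  expect_equal(ml$sd[2L]^2, sum((o - mean(o))^2) / (200 + 3),
               tolerance = 1e-9)
})

test_that("emission updates match the closed form on a hand case", {
  o <- c(1, 2, 3)
  prof <- list(cgh_profile("c", c(0, 400, 800), c(60, 460, 860), o))
  g <- cbind(c(1, .5, .25), c(0, .5, .5), c(0, 0, .25))
  hy <- list(emission = list(m = c(.5, 0, 0), tau = c(2, 1, 1),
                             a = c(2, 2, 2), b = c(.7, 1, 1)))
  res <- m_step_emissions(prof, list(g), hy)
  sg <- sum(g[, 1L]); so <- sum(g[, 1L] * o)
  mu <- (so + 2 * .5) / (sg + 2)
  sq <- sum(g[, 1L] * (o - mu)^2)
  s2 <- (2 * .7 + 2 * (mu - .5)^2 + sq) / (2 * 2 + 3 + sg)
  expect_equal(res$mean[1L], mu, tolerance = 1e-12)
  expect_equal(res$sd[1L], sqrt(s2), tolerance = 1e-12)
})

test_that("initialization anchors emissions and samples complete trees", {
  set.seed(2)
  o <- rnorm(5000)
  prof <- list(cgh_profile("c", (0:4999) * 350, (0:4999) * 350 + 60, o))
  m <- initialize_phhmm(prof, K = 3L, r = 2L, seed = 5)
  expect_equal(unname(m$emissions$mean[2L]), 0)
  expect_lt(abs(unname(m$emissions$sd[1L]) - 1), 0.05)
  expect_equal(unname(m$emissions$mean[1L]),
               quantile(o, .05, names = FALSE))
  ## initially a full higher-order HMM: complete trees, K^k leaves
  expect_equal(num_leaves(m$transitions[[1L]]$tree), 3L)
  expect_equal(num_leaves(m$transitions[[2L]]$tree), 9L)
  m2 <- initialize_phhmm(prof, K = 3L, r = 2L, seed = 5)
  expect_identical(m, m2)
  expect_error(initialize_phhmm(list(cgh_profile("c", 0, 60, 1)), K = 3L,
                                r = 1L), "distinct")
})

test_that("EM iterations never decrease the log-posterior", {
  set.seed(3)
  truth <- sticky_truth()
  ds <- generate_from_model(truth, 2, 300, seed = 20)
  for (r in 1:3) {
    hy <- make_hyper(unlist(lapply(ds$profiles, `[[`, "value")), r,
                     kappa = -2)
    for (start in 1:3) {
      m <- initialize_phhmm(ds$profiles, K = 3L, r = r, hyper = hy,
                            seed = 100 * r + start)
      lp_prev <- log_likelihood(m, ds$profiles) + log_prior(m, hy)
      for (it in 1:12) {
        step <- em_iteration(m, ds$profiles, hy)
        expect_gte(step$log_posterior, lp_prev - 1e-6)
        lp_prev <- step$log_posterior
        m <- step$model
      }
    }
  }
})

test_that("a converged model is an EM fixed point", {
  set.seed(4)
  ds <- generate_from_model(sticky_truth(), 2, 400, seed = 21)
  cfg <- fit_config(order = 1, kappa = 0, max_iterations = 100, tol = 1e-6,
                    seed = 9)
  res <- fit_phhmm(ds$profiles, cfg)
  hy <- make_hyper(unlist(lapply(ds$profiles, `[[`, "value")), 1, kappa = 0)
  step <- em_iteration(res$model, ds$profiles, hy)
  expect_lt(abs(step$log_posterior - res$log_posterior), 1e-4)
})

test_that("huge kappa reproduces classic higher-order Baum-Welch updates", {
  set.seed(5)
  ds <- generate_from_model(sticky_truth(), 1, 200, seed = 22)
  r <- 2L
  hy <- make_hyper(ds$profiles[[1L]]$value, r, kappa = 1e9)
  m0 <- initialize_phhmm(ds$profiles, K = 3L, r = r, hyper = hy, seed = 7)
  step <- em_iteration(m0, ds$profiles, hy)
  fb <- forward_backward(m0, ds$profiles[[1L]])
  for (k in 1:r) {
    ## complete tree selected; rows = (N + alpha) / row total
    expect_equal(num_leaves(step$model$transitions[[k]]$tree), 3L^k)
    manual <- fb$counts[[k]] + hy$transition[[k]]
    manual <- manual / rowSums(manual)
    expect_equal(unname(context_probs(step$model$transitions[[k]])),
                 unname(manual), tolerance = 1e-9)
  }
})

test_that("fit respects iteration limits and the convergence rule", {
  set.seed(6)
  ds <- generate_from_model(sticky_truth(), 1, 150, seed = 23)
  cfg1 <- fit_config(order = 1, max_iterations = 1, tol = 1e-3, seed = 2)
  res1 <- fit_phhmm(ds$profiles, cfg1)
  expect_equal(res1$iterations, 1L)
  expect_false(res1$converged)
  cfg2 <- fit_config(order = 1, max_iterations = 200, tol = 1, seed = 2)
  res2 <- fit_phhmm(ds$profiles, cfg2)
  expect_true(res2$converged)
  ## two-successive-steps rule: the last two improvements are < tol
  tr <- c(res2$log_posterior_init, res2$log_posterior_trace)
  imp <- diff(tr)
  n <- length(imp)
  expect_true(all(imp[c(n - 1L, n)] < 1))
  ## trace is non-decreasing within numerical slack
  expect_true(all(diff(res2$log_posterior_trace) > -1e-6))
})

test_that("order-0 training equals an independent MAP mixture EM", {
  set.seed(7)
  values <- c(rnorm(300, -1.5, .4), rnorm(700, 0, .3))[sample(1000)]
  prof <- list(cgh_profile("c", (0:999) * 350, (0:999) * 350 + 60, values))
  hy <- make_hyper(values, 0)
  cfg <- fit_config(order = 0, max_iterations = 15, tol = 1e-9, seed = 13)
  res <- fit_phhmm(prof, cfg, hyper = hy)
  m0 <- initialize_phhmm(prof, K = 3L, r = 0L, hyper = hy,
                         seed = phhmm:::restart_seed(13, 1))
  ref <- mixture_em_reference(values, m0, hy, length(res$log_posterior_trace))
  expect_equal(res$log_posterior_trace, ref$trace, tolerance = 1e-8)
})

test_that("restarts return the best final log-posterior deterministically", {
  set.seed(8)
  ds <- generate_from_model(sticky_truth(), 1, 200, seed = 24)
  cfg <- fit_config(order = 1, max_iterations = 10, tol = 1e-3, seed = 3,
                    n_restarts = 3)
  res <- fit_phhmm(ds$profiles, cfg)
  singles <- vapply(1:3, function(i) {
    ## same init as restart i of the multi-restart fit
    phhmm:::fit_one(ds$profiles,
                    fit_config(order = 1, max_iterations = 10, tol = 1e-3,
                               seed = 3),
                    make_hyper(ds$profiles[[1L]]$value, 1),
                    c("del", "neutral", "amp"),
                    phhmm:::restart_seed(3, i))$log_posterior
  }, 0)
  expect_equal(res$log_posterior, max(singles), tolerance = 1e-9)
})

test_that("label anchoring relabels swapped components by mean order", {
  set.seed(9)
  m <- random_model(K = 3L, r = 2L, mean = c(-1, 0, 1), sd = c(.4, .4, .4))
  perm <- c(2L, 3L, 1L)
  swapped <- phhmm:::permute_phhmm(m, perm)
  expect_equal(unname(swapped$emissions$mean), c(0, 1, -1))
  fixed <- phhmm:::relabel_by_mean(swapped)
  expect_equal(unname(fixed$emissions$mean), c(-1, 0, 1))
  ## permutation preserves the distribution: identical likelihoods
  o <- rnorm(30)
  expect_equal(log_likelihood(fixed, cgh_profile("c", (0:29) * 10, (0:29) * 10 + 5, o)),
               log_likelihood(m, cgh_profile("c", (0:29) * 10, (0:29) * 10 + 5, o)),
               tolerance = 1e-9)
})

test_that("the scan schedule expands orders x kappas x restarts", {
  sched <- kappa_scan_schedule(orders = 3L, kappa_grid = seq(-100, 0,
                                                            length.out = 40),
                               n_restarts = 20L)
  expect_equal(nrow(sched), 800L)
  expect_equal(nrow(kappa_scan_schedule(1L, 0, 1L)), 1L)
  expect_error(kappa_scan_schedule(integer(0), 0, 1L), "non-empty")
})

test_that("a minimal kappa scan runs and records complexities", {
  set.seed(10)
  ds <- generate_from_model(sticky_truth(), 1, 150, seed = 25)
  sc <- kappa_scan(ds$profiles, orders = 1L, kappa_grid = c(-1e6, 0),
                   n_restarts = 1L, seed = 4, max_iterations = 5)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$leaves[sc$kappa == -1e6], 1L)
  expect_true(all(c("order", "kappa", "restart", "leaves", "log_posterior",
                    "converged", "iterations") %in% names(sc)))
})
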