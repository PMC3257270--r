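## Shared fixtures and independent oracles.  Everything here is brute force
## or closed form, deliberately independent of the package's recursions.

## random transition matrix on a complete tree of height k
random_complete_tm <- function(K, k) {
  tree <- build_complete_tree(K, k)
  probs <- matrix(rgamma(K^k * K, 1), K^k)
  probs <- probs / rowSums(probs)
  transition_matrix(tree, probs)
}

random_model <- function(K = 3L, r = 2L, mean = NULL, sd = NULL) {
  if (is.null(mean)) mean <- sort(rnorm(K, 0, 1.5))
  if (is.null(sd)) sd <- runif(K, 0.3, 1)
  init <- rgamma(K, 1); init <- init / sum(init)
  trans <- if (r > 0L) lapply(seq_len(r), function(k) random_complete_tm(K, k))
           else list()
  phhmm(states = if (K == 3L) c("del", "neutral", "amp") else paste0("s", 1:K),
        order = r, initial = init, transitions = trans, mean = mean, sd = sd)
}

## order-2-but-really-first-order sticky truth used across training tests:
## the height-2 tree splits on the most recent state only (3 leaves)
sticky_truth <- function() {
  rows1 <- matrix(c(.85, .14, .01,
                    .03, .94, .03,
                    .01, .14, .85), 3, byrow = TRUE)
  A1 <- transition_matrix(build_complete_tree(3, 1), rows1)
  node2 <- list(blocks = list(1L, 2L, 3L), children = list(
    list(blocks = list(1:3), children = list(NULL)),
    list(blocks = list(1:3), children = list(NULL)),
    list(blocks = list(1:3), children = list(NULL))))
  tree2 <- phhmm:::new_context_tree(node2, 3L, 2L, c("del", "neutral", "amp"))
  A2 <- transition_matrix(tree2, rows1)
  phhmm(order = 2, initial = c(.05, .9, .05), transitions = list(A1, A2),
        mean = c(-1.5, 0, 1.5), sd = c(.4, .2, .4))
}

## exhaustive-enumeration oracle: joint probability of every state path,
## hence exact log-likelihood, posteriors and expected transition counts
enumeration_oracle <- function(model, values) {
  K <- model$states$K
  r <- model$order
  T <- length(values)
  P <- lapply(model$transitions, context_probs)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  pj <- apply(seqs, 1L, function(q) {
    p <- model$initial[q[1L]]
    if (T >= 2L) {
      for (t in 2:T) {
        k <- min(t - 1L, r)
        if (k == 0L) {
          p <- p * model$initial[q[t]]
        } else {
          ctx <- q[(t - 1):(t - k)]
          p <- p * P[[k]][context_code(ctx, K), q[t]]
        }
      }
    }
    p * prod(dnorm(values, model$emissions$mean[q], model$emissions$sd[q]))
  })
  loglik <- log(sum(pj))
  w <- pj / sum(pj)
  gamma <- vapply(seq_len(K), function(i) {
    vapply(seq_len(T), function(t) sum(w[seqs[, t] == i]), 0)
  }, numeric(T))
  gamma <- matrix(gamma, T, K)
  counts <- lapply(seq_len(r), function(k) matrix(0, K^k, K))
  if (r > 0L && T >= 2L) {
    for (s in seq_len(nrow(seqs))) {
      q <- seqs[s, ]
      for (t in 2:T) {
        k <- min(t - 1L, r)
        cc <- context_code(q[(t - 1):(t - k)], K)
        counts[[k]][cc, q[t]] <- counts[[k]][cc, q[t]] + w[s]
      }
    }
  }
  list(loglik = loglik, gamma = gamma, counts = counts)
}

## brute-force best tree by scoring every enumerable tree
exhaustive_best_tree <- function(counts, alpha, kappa, K, k) {
  trees <- enumerate_trees(K, k)
  scores <- vapply(trees, score_tree, 0, counts = counts, alpha = alpha,
                   kappa = kappa)
  list(score = max(scores), tree = trees[[which.max(scores)]],
       scores = scores)
}

## Durbin-Levinson partial autocorrelations, hand-coded
durbin_levinson_pacf <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  acov <- vapply(0:max_lag, function(h) {
    sum(x[1:(n - h)] * x[(1 + h):n]) / n
  }, 0)
  rho <- acov[-1L] / acov[1L]
  phi <- matrix(0, max_lag, max_lag)
  phi[1L, 1L] <- rho[1L]
  if (max_lag > 1L) {
    for (m in 2:max_lag) {
      num <- rho[m] - sum(phi[m - 1L, 1:(m - 1L)] * rho[(m - 1L):1L])
      den <- 1 - sum(phi[m - 1L, 1:(m - 1L)] * rho[1:(m - 1L)])
      phi[m, m] <- num / den
      for (j in 1:(m - 1L)) {
        phi[m, j] <- phi[m - 1L, j] - phi[m, m] * phi[m - 1L, m - j]
      }
    }
  }
  diag(phi)
}

## independently coded MAP Gaussian-mixture EM (order-0 reference)
mixture_em_reference <- function(values, model0, hyper, n_iter) {
  K <- length(model0$initial)
  pi_ <- unname(model0$initial)
  mu <- unname(model0$emissions$mean)
  sdv <- unname(model0$emissions$sd)
  em <- hyper$emission
  lp_of <- function(pi_, mu, sdv) {
    dens <- vapply(1:K, function(i) dnorm(values, mu[i], sdv[i]), numeric(length(values)))
    ll <- sum(log(dens %*% pi_))
    pr <- sum(hyper$initial * log(pi_)) -
      (sum(lgamma(hyper$initial)) - lgamma(sum(hyper$initial)))
    for (i in 1:K) {
      s2 <- sdv[i]^2
      pr <- pr + em$a[i] * log(em$b[i]) - lgamma(em$a[i]) -
        (em$a[i] + 1) * log(s2) - em$b[i] / s2 +
        0.5 * (log(em$tau[i]) - log(2 * pi) - log(s2)) -
        em$tau[i] * (mu[i] - em$m[i])^2 / (2 * s2)
    }
    ll + pr
  }
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    dens <- vapply(1:K, function(i) dnorm(values, mu[i], sdv[i]), numeric(length(values)))
    w <- sweep(dens, 2L, pi_, `*`)
    g <- w / rowSums(w)
    sg <- colSums(g)
    pi_ <- (sg + hyper$initial) / sum(sg + hyper$initial)
    mu <- (colSums(g * values) + em$tau * em$m) / (sg + em$tau)
    sq <- colSums(g * (outer(values, mu, `-`))^2)
    s2 <- (2 * em$b + em$tau * (mu - em$m)^2 + sq) / (2 * em$a + 3 + sg)
    sdv <- sqrt(s2)
    trace[it] <- lp_of(pi_, mu, sdv)
  }
  list(trace = trace, pi = pi_, mean = mu, sd = sdv)
}

## stationary distribution of the expanded first-order chain over r-tuples
stationary_state_distribution <- function(model) {
  K <- model$states$K
  r <- model$order
  M <- K^r
  P <- context_probs(model$transitions[[r]])
  TP <- matrix(0, M, M)
  for (u in 1:M) {
    for (j in 1:K) {
      v <- ((u - 1L) %% (M / K)) * K + j   # shift context, newest in low digit
      TP[u, v] <- TP[u, v] + P[u, j]
    }
  }
  e <- eigen(t(TP))
  i <- which.min(abs(e$values - 1))
  st <- Re(e$vectors[, i]); st <- st / sum(st)
  vapply(1:K, function(i) sum(st[((1:M) - 1L) %% K + 1L == i]), 0)
}
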