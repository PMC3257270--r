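#' Hyperparameters of the conjugate prior
#'
#' The prior over the full parameter bundle factorizes into (i) a
#' transformed Dirichlet over the initial distribution with pseudocounts
#' `initial`, (ii) per transition matrix a transformed Dirichlet over leaf
#' probability vectors (pseudocounts aggregated from the per-context tables
#' `transition[[k]]`) together with the tree-structure prior
#' `exp(kappa * num_leaves)`, and (iii) per state a Normal-scaled-Inverse-
#' Gamma over (mean, variance) with location `m`, strength `tau`, shape `a`
#' and scale `b`.  "Transformed" means the Dirichlet is parameterized in
#' log-space, so the density exponent of probability p_j is the pseudocount
#' a_j itself (not a_j - 1) and the MAP estimate is the pseudocount-smoothed
#' frequency without subtracting one.
#'
#' @param initial positive per-state pseudocounts for the initial
#'   distribution.
#' @param transition list over k = 1..r of `K^k x K` positive pseudocount
#'   matrices in context-code row order.
#' @param kappa tree-structure hyper-parameter (natural-log units): the
#'   unnormalized log tree prior is `kappa * num_leaves`.  Negative values
#'   favour parsimonious trees; strongly negative values drive selection to
#'   the fused tree (mixture-like sharing), large positive values to the
#'   complete tree (full higher-order HMM).
#' @param emission list with numeric per-state vectors `m` (prior mean
#'   location), `tau >= 0` (prior strength), `a > 0` (shape), `b > 0`
#'   (scale).
#' @return object of class `phhmm_hyper`.
#' @export
hyperparameters <- function(initial, transition, kappa, emission) {
  initial <- as.numeric(initial)
  if (any(initial <= 0)) stop("initial pseudocounts must be > 0", call. = FALSE)
  for (k in seq_along(transition)) {
    al <- transition[[k]]
    if (!is.matrix(al) || any(al <= 0)) {
      stop("transition pseudocounts must be positive matrices", call. = FALSE)
    }
    K <- length(initial)
    if (nrow(al) != K^k || ncol(al) != K) {
      stop("transition pseudocount matrix ", k, " must be K^k x K",
           call. = FALSE)
    }
  }
  with(emission, {
    if (any(tau < 0) || any(a <= 0) || any(b <= 0)) {
      stop("emission prior needs tau >= 0, a > 0, b > 0", call. = FALSE)
    }
  })
  structure(list(initial = initial, transition = transition,
                 kappa = as.numeric(kappa), emission = emission),
            class = "phhmm_hyper")
}

#' Default hyperparameters
#'
#' Weak, order-balanced defaults: one pseudocount per initial state;
#' `alpha^(k)(c, j) = K^(-k)` so each order contributes total pseudocount
#' mass K; emission locations at the initialization anchors (a low
#' quantile, zero, a high quantile of the pooled log-ratios), `tau = 1`,
#' `a = 2`, `b` equal to the pooled data variance; `kappa = 0`.
#'
#' @param values pooled log-ratios (used to anchor the emission prior).
#' @param K number of states.
#' @param order model order r (how many transition pseudocount tables).
#' @param kappa tree-structure hyper-parameter.
#' @param anchor_probs quantile anchors for the emission locations when
#'   `K = 3` they are (low, 0.5 -> forced to zero, high).
#' @return `phhmm_hyper`.
#' @export
default_hyperparameters <- function(values, K = 3L, order = 1L, kappa = 0,
                                    anchor_probs = c(0.05, 0.95)) {
  values <- as.numeric(values)
  m <- emission_anchors(values, K, anchor_probs)
  transition <- lapply(seq_len(order), function(k) {
    matrix(K^(-k), nrow = K^k, ncol = K)
  })
  hyperparameters(
    initial = rep(1, K),
    transition = transition,
    kappa = kappa,
    emission = list(m = m, tau = rep(1, K), a = rep(2, K),
                    b = rep(max(var(values), 1e-8), K))
  )
}

## Anchors: lowest state at a low quantile, middle state pinned at zero
## (unchanged regions), highest at a high quantile; for K != 3, equally
## spaced quantiles.
emission_anchors <- function(values, K, anchor_probs = c(0.05, 0.95)) {
  if (K == 3L) {
    c(min(quantile(values, anchor_probs[1L], names = FALSE), -1e-3), 0,
      max(quantile(values, anchor_probs[2L], names = FALSE), 1e-3))
  } else {
    quantile(values, seq(0.05, 0.95, length.out = K), names = FALSE)
  }
}

#' Aggregate per-context pseudocounts onto the leaves of a tree
#'
#' The pseudocount vector of a leaf is the sum of the pseudocount rows of
#' all concrete contexts it represents, so total pseudocount mass is
#' conserved for every tree and the complete tree reduces to the identity.
#'
#' @param alpha `K^k x K` positive matrix in context-code row order.
#' @param tree a `context_tree` of height k.
#' @return `num_leaves x K` matrix.
#' @export
aggregate_pseudocounts <- function(alpha, tree) {
  stopifnot(inherits(tree, "context_tree"))
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != tree$K^tree$height || ncol(alpha) != tree$K) {
    stop("alpha must be defined for all K^k contexts", call. = FALSE)
  }
  if (any(alpha <= 0)) stop("pseudocounts must be strictly positive", call. = FALSE)
  agg <- rowsum(alpha, tree$context_map, reorder = TRUE)
  rownames(agg) <- tree$leaf_ids[as.integer(rownames(agg))]
  agg
}

#' Unnormalized log tree-structure prior
#'
#' `kappa * num_leaves(tree)` in natural-log units: decreasing in the leaf
#' count for `kappa < 0`, increasing for `kappa > 0`.
#'
#' @param tree a `context_tree`.
#' @param kappa tree-structure hyper-parameter.
#' @return numeric.
#' @export
log_tree_structure_prior <- function(tree, kappa) {
  kappa * num_leaves(tree)
}

## log normalizer of a (transformed) Dirichlet: log Z(a) with
## Z(a) = prod Gamma(a_j) / Gamma(sum a_j)
log_dirichlet_z <- function(a) sum(lgamma(a)) - lgamma(sum(a))

## one transformed-Dirichlet log density term: sum_j a_j log p_j - log Z(a)
log_tdirichlet <- function(p, a) {
  lp <- ifelse(p > 0, log(p), -Inf)
  s <- sum(a * lp)
  if (!is.finite(s)) return(-Inf)
  s - log_dirichlet_z(a)
}

#' Log prior of a transition matrix set
#'
#' Sum over matrices and leaves of transformed-Dirichlet terms on the
#' aggregated pseudocounts, plus `kappa * num_leaves` per matrix.  A zero
#' probability facing a positive pseudocount yields `-Inf`.
#'
#' @param transitions list of `phhmm_transitions` (heights 1..r).
#' @param hyper a `phhmm_hyper` with tables for every order.
#' @return numeric (possibly `-Inf`).
#' @export
log_transition_prior <- function(transitions, hyper) {
  total <- 0
  for (k in seq_along(transitions)) {
    tm <- transitions[[k]]
    a <- aggregate_pseudocounts(hyper$transition[[k]], tm$tree)
    for (l in seq_len(nrow(a))) {
      total <- total + log_tdirichlet(tm$probs[l, ], a[l, ])
    }
    total <- total + log_tree_structure_prior(tm$tree, hyper$kappa)
  }
  total
}

## per-state Normal-scaled-Inverse-Gamma log density on (mu, sigma^2)
log_nig <- function(mu, sigma2, m, tau, a, b) {
  out <- a * log(b) - lgamma(a) - (a + 1) * log(sigma2) - b / sigma2
  if (tau > 0) {
    out <- out + 0.5 * (log(tau) - log(2 * pi) - log(sigma2)) -
      tau * (mu - m)^2 / (2 * sigma2)
  }
  out
}

#' Log prior density of a model
#'
#' Product prior: transformed Dirichlet on the initial distribution,
#' transition prior (with tree-structure terms) and per-state
#' Normal-scaled-Inverse-Gamma emission terms.
#'
#' @param model a [phhmm].
#' @param hyper a `phhmm_hyper`.
#' @return numeric log density (unnormalized in the tree structure).
#' @export
log_prior <- function(model, hyper) {
  total <- log_tdirichlet(unname(model$initial), hyper$initial)
  if (model$order > 0L) {
    total <- total + log_transition_prior(model$transitions, hyper)
  }
  em <- hyper$emission
  for (i in seq_len(model$states$K)) {
    total <- total + log_nig(model$emissions$mean[i], model$emissions$sd[i]^2,
                             em$m[i], em$tau[i], em$a[i], em$b[i])
  }
  unname(total)
}

rdirichlet1 <- function(a) {
  g <- rgamma(length(a), shape = a, rate = 1)
  if (sum(g) <= 0) {                      # extreme shapes; retry via max
    g[which.max(a)] <- 1
  }
  g / sum(g)
}

#' Sample initial and transition parameters from the prior
#'
#' Used for model initialization: the initial distribution is drawn from
#' Dirichlet(initial pseudocounts) and every transition row of a complete
#' state-context tree of each height k = 1..r from Dirichlet(alpha row), so
#' the initial model represents a full higher-order HMM.  Emission
#' parameters are not sampled; they are set from the data (see
#' [initialize_phhmm()]).
#'
#' @param hyper a `phhmm_hyper` with tables up to order `r`.
#' @param K number of states.
#' @param r model order.
#' @param states state labels.
#' @param seed optional integer seed.
#' @return list with `initial` (length K) and `transitions` (list of
#'   `phhmm_transitions` on complete trees; empty for `r = 0`).
#' @export
sample_from_prior <- function(hyper, K, r, states = default_labels(K),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  initial <- rdirichlet1(hyper$initial)
  transitions <- list()
  if (r > 0L) {
    transitions <- lapply(seq_len(r), function(k) {
      tree <- build_complete_tree(K, k, states)
      al <- hyper$transition[[k]]
      probs <- t(apply(al, 1L, rdirichlet1))
      transition_matrix(tree, probs)
    })
  }
  list(initial = initial, transitions = transitions)
}
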