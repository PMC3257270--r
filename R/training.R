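#' Fit configuration
#'
#' @param order model order r >= 0.
#' @param kappa tree-structure hyper-parameter used during training
#'   (overrides the value stored in the hyperparameters).
#' @param max_iterations maximum EM iterations (>= 1).
#' @param tol minimum log-posterior improvement; training stops once the
#'   improvement is below `tol` for two successive iteration steps.
#' @param seed integer seed governing initialization (and restart seeds).
#' @param n_restarts number of independent initializations; the restart
#'   with the highest final log-posterior is returned.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(order, kappa = 0, max_iterations = 100L, tol = 1e-3,
                       seed = 1L, n_restarts = 1L) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (order < 0 || order != round(order)) stop("order must be >= 0", call. = FALSE)
  structure(list(order = as.integer(order), kappa = as.numeric(kappa),
                 max_iterations = as.integer(max_iterations),
                 tol = as.numeric(tol), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "fit_config")
}

## deterministic restart -> seed mapping (kept below 2^31); results are
## identical for a given (seed, restart index) regardless of run order
restart_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 104729 * (idx - 1)) %% 2147483647)
}

#' Initialize a model from data
#'
#' Emission means are anchored at a low quantile of the pooled log-ratios
#' (deletions), zero (unchanged regions) and a high quantile
#' (amplifications); all standard deviations start at the pooled data
#' standard deviation.  The initial distribution and every transition row
#' of complete state-context trees are sampled from the prior, so the
#' initial model represents a full higher-order HMM.
#'
#' @param profiles profile list.
#' @param K number of states (default 3).
#' @param r model order.
#' @param hyper `phhmm_hyper` (default: [default_hyperparameters()] on the
#'   pooled values).
#' @param seed integer seed for the prior draws.
#' @param states state labels.
#' @param anchor_probs quantile anchors for the outer states.
#' @return a [phhmm].
#' @export
initialize_phhmm <- function(profiles, K = 3L, r, hyper = NULL, seed = NULL,
                             states = default_labels(K),
                             anchor_probs = c(0.05, 0.95)) {
  profiles <- as_profile_list(profiles)
  values <- unlist(lapply(profiles, `[[`, "value"))
  if (length(unique(values)) < K) {
    stop("need at least K distinct log-ratios to initialize", call. = FALSE)
  }
  if (is.null(hyper)) {
    hyper <- default_hyperparameters(values, K, order = max(r, 1L),
                                     anchor_probs = anchor_probs)
  }
  mean <- emission_anchors(values, K, anchor_probs)
  s <- max(sd(values), 1e-6)
  drawn <- sample_from_prior(hyper, K, r, states, seed = seed)
  phhmm(states = states, order = r, initial = drawn$initial,
        transitions = drawn$transitions, mean = mean, sd = rep(s, K))
}

#' MAP update of the initial distribution
#'
#' `pi_i` proportional to expected count plus pseudocount (no "-1": the
#' prior is the log-space-parameterized Dirichlet).
#'
#' @param counts nonnegative expected initial-state counts.
#' @param hyper `phhmm_hyper`.
#' @return normalized probability vector.
#' @export
m_step_initial <- function(counts, hyper) {
  w <- counts + hyper$initial
  w / sum(w)
}

#' MAP update of the Gaussian emission parameters
#'
#' Joint posterior mode of the per-state Normal-scaled-Inverse-Gamma:
#' `mu = (sum gamma o + tau m) / (sum gamma + tau)` and
#' `sigma^2 = (2 b + tau (mu - m)^2 + sum gamma (o - mu)^2) /
#' (2 a + 3 + sum gamma)`.  The positive scale `b` keeps variances from
#' collapsing on empty states.
#'
#' @param profiles profile list.
#' @param posteriors list of T x K posterior matrices aligned with
#'   `profiles`.
#' @param hyper `phhmm_hyper`.
#' @return list with per-state `mean` and `sd`.
#' @export
m_step_emissions <- function(profiles, posteriors, hyper) {
  profiles <- as_profile_list(profiles)
  K <- ncol(posteriors[[1L]])
  sg <- numeric(K); so <- numeric(K)
  for (i in seq_along(profiles)) {
    g <- posteriors[[i]]
    o <- profiles[[i]]$value
    sg <- sg + colSums(g)
    so <- so + colSums(g * o)
  }
  em <- hyper$emission
  mu <- (so + em$tau * em$m) / (sg + em$tau)
  sq <- numeric(K)
  for (i in seq_along(profiles)) {
    g <- posteriors[[i]]
    o <- profiles[[i]]$value
    sq <- sq + colSums(g * (outer(o, mu, `-`))^2)
  }
  sigma2 <- (2 * em$b + em$tau * (mu - em$m)^2 + sq) / (2 * em$a + 3 + sg)
  list(mean = mu, sd = sqrt(sigma2))
}

#' One Bayesian Baum-Welch iteration
#'
#' Expectation step by [forward_backward()] over all profiles (counts
#' summed across chromosomes), then closed-form MAP updates for the initial
#' distribution and emissions and, for every height k = 1..r, exact
#' selection of the optimal state-context tree and its transition rows by
#' [select_optimal_tree()].  Because each maximization is exact, the
#' log-posterior is non-decreasing across iterations.
#'
#' @param model current [phhmm].
#' @param profiles profile list.
#' @param hyper `phhmm_hyper` (its `kappa` is the tree-structure weight).
#' @return list with `model` (updated), `log_posterior` (of the updated
#'   model) and `loglik_prev` (log-likelihood of the incoming model, a
#'   by-product of the E-step).
#' @export
em_iteration <- function(model, profiles, hyper) {
  profiles <- as_profile_list(profiles)
  K <- model$states$K
  r <- model$order
  init_counts <- numeric(K)
  counts <- if (r > 0L) lapply(seq_len(r), function(k) matrix(0, K^k, K))
            else list()
  posteriors <- vector("list", length(profiles))
  loglik_prev <- 0
  for (i in seq_along(profiles)) {
    fb <- forward_backward(model, profiles[[i]])
    loglik_prev <- loglik_prev + fb$loglik
    init_counts <- init_counts + fb$init_counts
    posteriors[[i]] <- fb$gamma
    for (k in seq_len(length(fb$counts))) {
      counts[[k]] <- counts[[k]] + fb$counts[[k]]
    }
  }

  initial <- m_step_initial(init_counts, hyper)
  emis <- m_step_emissions(profiles, posteriors, hyper)
  transitions <- list()
  if (r > 0L) {
    transitions <- lapply(seq_len(r), function(k) {
      ts <- select_optimal_tree(counts[[k]], hyper$transition[[k]],
                                hyper$kappa, K, k, model$states$labels)
      transition_matrix(ts$tree, ts$leaf_probs)
    })
  }
  new_model <- phhmm(states = model$states, order = r, initial = initial,
                     transitions = transitions, mean = emis$mean,
                     sd = emis$sd)
  lp <- log_likelihood(new_model, profiles) + log_prior(new_model, hyper)
  list(model = new_model, log_posterior = lp, loglik_prev = loglik_prev)
}

#' Fit a parsimonious higher-order HMM
#'
#' Runs Bayesian Baum-Welch EM from a data-driven initialization until the
#' log-posterior improves by less than `tol` for two successive iterations
#' or `max_iterations` is reached.  With several restarts, each restart
#' draws its own initial parameters from the prior under a seed derived
#' deterministically from `(seed, restart index)`, and the restart with the
#' highest final log-posterior is returned.  If EM leaves the emission
#' means out of order, states are relabeled by increasing mean at output
#' time.
#'
#' @param profiles a [cgh_profile] or list of them (chromosomes are
#'   independent sequences).
#' @param config a [fit_config].
#' @param hyper optional `phhmm_hyper`; defaults to
#'   [default_hyperparameters()] with `config$kappa`.
#' @param states state labels.
#' @return object of class `phhmm_fit`: list with `model`,
#'   `log_posterior_trace`, `log_posterior_init`, `converged`,
#'   `iterations`, `selected_trees`, `restart`, `config`.
#' @export
fit_phhmm <- function(profiles, config, hyper = NULL,
                      states = default_labels(3L)) {
  stopifnot(inherits(config, "fit_config"))
  profiles <- as_profile_list(profiles)
  values <- unlist(lapply(profiles, `[[`, "value"))
  K <- length(states)
  if (is.null(hyper)) {
    hyper <- default_hyperparameters(values, K, order = max(config$order, 1L))
  }
  hyper$kappa <- config$kappa

  best <- NULL
  for (rs in seq_len(config$n_restarts)) {
    res <- fit_one(profiles, config, hyper, states,
                   restart_seed(config$seed, rs))
    res$restart <- rs
    if (is.null(best) || res$log_posterior > best$log_posterior) best <- res
  }
  best$config <- config
  best
}

fit_one <- function(profiles, config, hyper, states, seed) {
  model <- initialize_phhmm(profiles, K = length(states), r = config$order,
                            hyper = hyper, seed = seed, states = states)
  lp0 <- log_likelihood(model, profiles) + log_prior(model, hyper)
  trace <- numeric(0)
  converged <- FALSE
  prev <- lp0
  small_steps <- 0L
  for (it in seq_len(config$max_iterations)) {
    step <- em_iteration(model, profiles, hyper)
    model <- step$model
    trace <- c(trace, step$log_posterior)
    if (!is.finite(step$log_posterior)) {
      stop("non-finite log-posterior during EM", call. = FALSE)
    }
    if (step$log_posterior - prev < config$tol) {
      small_steps <- small_steps + 1L
    } else {
      small_steps <- 0L
    }
    prev <- step$log_posterior
    if (small_steps >= 2L) {
      converged <- TRUE
      break
    }
  }
  model <- relabel_by_mean(model)
  structure(list(model = model, log_posterior = prev,
                 log_posterior_trace = trace, log_posterior_init = lp0,
                 converged = converged, iterations = length(trace),
                 selected_trees = lapply(model$transitions, `[[`, "tree"),
                 seed = seed),
            class = "phhmm_fit")
}

#' @export
print.phhmm_fit <- function(x, ...) {
  cat(sprintf("phhmm fit: order %d, %d iterations, %sconverged, log-posterior %.3f\n",
              x$model$order, x$iterations, if (x$converged) "" else "NOT ",
              x$log_posterior))
  if (x$model$order > 0L) {
    cat("  selected complexity (leaves):",
        paste(vapply(x$selected_trees, num_leaves, 1L), collapse = ", "), "\n")
  }
  invisible(x)
}

## Relabel states so emission means are increasing in state order; the
## label-anchoring convention (del < neutral < amp) is enforced at
## initialization only, so EM may occasionally swap components.
relabel_by_mean <- function(model) {
  perm <- order(model$emissions$mean)
  if (identical(perm, seq_along(perm))) return(model)
  permute_phhmm(model, perm)
}

permute_phhmm <- function(model, perm) {
  K <- model$states$K
  inv <- order(perm)
  map_node <- function(node) {
    if (is.null(node)) return(NULL)
    blocks <- lapply(node$blocks, function(B) sort(inv[B]))
    ord <- order(vapply(blocks, min, 1L))
    list(blocks = blocks[ord], children = node$children[ord] |>
           lapply(map_node))
  }
  transitions <- lapply(model$transitions, function(tm) {
    k <- tm$tree$height
    tree <- new_context_tree(map_node(tm$tree$root), K, k,
                             model$states$labels)
    Pold <- context_probs(tm)
    ctab <- context_table(K, k)
    oldcode <- as.integer(1L + (matrix(perm[ctab], ncol = k) - 1L) %*%
                            K^(seq_len(k) - 1L))
    Pnew <- Pold[oldcode, perm, drop = FALSE]
    probs <- Pnew[match(seq_len(tree$n_leaves), tree$context_map), ,
                  drop = FALSE]
    transition_matrix(tree, probs)
  })
  phhmm(states = model$states, order = model$order,
        initial = unname(model$initial)[perm], transitions = transitions,
        mean = unname(model$emissions$mean)[perm],
        sd = unname(model$emissions$sd)[perm])
}

#' Schedule of a complexity scan
#'
#' Expands orders, tree-structure hyper-parameter values and restarts into
#' one row per planned fit; with 40 kappa values and 20 restarts this
#' schedules 800 fits per order.
#'
#' @param orders integer vector of model orders.
#' @param kappa_grid numeric vector of kappa values.
#' @param n_restarts restarts per (order, kappa).
#' @return data.frame with columns `order`, `kappa`, `restart`.
#' @export
kappa_scan_schedule <- function(orders, kappa_grid, n_restarts) {
  if (length(orders) == 0L || length(kappa_grid) == 0L || n_restarts < 1) {
    stop("orders, kappa_grid and n_restarts must be non-empty", call. = FALSE)
  }
  out <- expand.grid(restart = seq_len(n_restarts), kappa = kappa_grid,
                     order = orders, KEEP.OUT.ATTRS = FALSE)
  out[, c("order", "kappa", "restart")]
}

#' Scan model complexities over a kappa grid
#'
#' Fits `n_restarts` models for every (order, kappa) pair and records the
#' selected complexity (leaves of the height-r tree) and final
#' log-posterior.  Restart seeds depend only on `(seed, restart)`, so the
#' same initializations are compared across the kappa grid.
#'
#' @inheritParams kappa_scan_schedule
#' @param profiles profile list.
#' @param hyper optional `phhmm_hyper` template (kappa is overridden per
#'   run).
#' @param seed base seed.
#' @param max_iterations,tol EM controls per fit.
#' @param keep_models if `TRUE`, fitted models are attached as a list
#'   column.
#' @return data.frame with one row per fit: `order`, `kappa`, `restart`,
#'   `leaves`, `log_posterior`, `converged`, `iterations` (and `fit` if
#'   `keep_models`).
#' @export
kappa_scan <- function(profiles, orders, kappa_grid, n_restarts = 1L,
                       hyper = NULL, seed = 1L, max_iterations = 50L,
                       tol = 1e-3, keep_models = FALSE) {
  sched <- kappa_scan_schedule(orders, kappa_grid, n_restarts)
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    cfg <- fit_config(order = sched$order[i], kappa = sched$kappa[i],
                      max_iterations = max_iterations, tol = tol,
                      seed = restart_seed(seed, sched$restart[i]),
                      n_restarts = 1L)
    res <- fit_phhmm(profiles, cfg, hyper = hyper)
    leaves <- if (res$model$order > 0L) {
      num_leaves(res$selected_trees[[res$model$order]])
    } else 1L
    rows[[i]] <- data.frame(order = sched$order[i], kappa = sched$kappa[i],
                            restart = sched$restart[i], leaves = leaves,
                            log_posterior = res$log_posterior,
                            converged = res$converged,
                            iterations = res$iterations)
    if (keep_models) rows[[i]]$fit <- I(list(res))
  }
  do.call(rbind, rows)
}
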