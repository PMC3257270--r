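## Emission densities with per-position rescaling.  Row t is multiplied by
## exp(-m_t) where m_t is the row max of the log densities; the forward
## scaling constants absorb the factor, and sum(m_t) is added back to the
## log-likelihood.  Posteriors and expected counts are unaffected.
emission_dens <- function(model, values) {
  K <- model$states$K
  ld <- vapply(seq_len(K), function(i) {
    dnorm(values, model$emissions$mean[i], model$emissions$sd[i], log = TRUE)
  }, numeric(length(values)))
  ld <- matrix(ld, nrow = length(values), ncol = K)
  if (any(!is.finite(ld) & !(ld == -Inf))) {
    stop("non-finite emission density", call. = FALSE)
  }
  m <- apply(ld, 1L, max)
  if (any(!is.finite(m))) stop("emission density underflow", call. = FALSE)
  list(dens = exp(ld - m), logshift = sum(m))
}

expanded_transitions <- function(model) {
  lapply(model$transitions, context_probs)
}

fb_order0 <- function(model, values) {
  ed <- emission_dens(model, values)
  w <- sweep(ed$dens, 2L, model$initial, `*`)
  rs <- rowSums(w)
  if (any(rs <= 0)) stop("forward pass underflow", call. = FALSE)
  gamma <- w / rs
  colnames(gamma) <- model$states$labels
  list(loglik = sum(log(rs)) + ed$logshift, gamma = gamma,
       counts = list(), init_counts = colSums(gamma))
}

#' Forward-backward pass for one profile
#'
#' Computes the exact log-likelihood, per-position state posteriors
#' `gamma[t, i] = P(q_t = i | O)` and expectation-step transition counts
#' `N^(k)(c, j)` for every order k = 1..r under a parsimonious higher-order
#' HMM.  The order-r chain is expanded to a first-order chain over tuples of
#' the r most recent states; positions t <= r use the height-min(t, r)
#' matrix with the available shorter context.  Per-position scaling keeps
#' the recursion stable on profiles of 1e5+ tiles.
#'
#' @param model a [phhmm] object.
#' @param profile a [cgh_profile] (or bare numeric vector of log-ratios).
#' @return list with `loglik`, `gamma` (T x K matrix), `counts` (list of
#'   `K^k x K` context-indexed expected transition counts, k = 1..r) and
#'   `init_counts` (expected initial-state counts, i.e. `gamma[1, ]`).
#' @export
forward_backward <- function(model, profile) {
  values <- if (inherits(profile, "cgh_profile")) profile$value else as.numeric(profile)
  if (length(values) < 1L) stop("profile must have length >= 1", call. = FALSE)
  if (model$order == 0L) return(fb_order0(model, values))
  ed <- emission_dens(model, values)
  res <- .fb_cpp(ed$dens, unname(model$initial), expanded_transitions(model),
                 model$order, TRUE)
  res$loglik <- res$loglik + ed$logshift
  ## round-off can leave posteriors epsilon outside [0, 1]
  res$gamma[res$gamma < 0] <- 0
  res$gamma[res$gamma > 1] <- 1
  colnames(res$gamma) <- model$states$labels
  names(res$init_counts) <- model$states$labels
  res$counts <- lapply(res$counts, function(m) {
    colnames(m) <- model$states$labels
    m
  })
  res
}

#' Total log-likelihood of profiles under a model
#'
#' Chromosome profiles are treated as independent sequences.
#'
#' @param model a [phhmm].
#' @param profiles a [cgh_profile] or non-empty list of them.
#' @return sum over profiles of `log P(O | model)`.
#' @export
log_likelihood <- function(model, profiles) {
  profiles <- as_profile_list(profiles)
  total <- 0
  for (p in profiles) {
    if (model$order == 0L) {
      total <- total + fb_order0(model, p$value)$loglik
    } else {
      ed <- emission_dens(model, p$value)
      res <- .fb_cpp(ed$dens, unname(model$initial),
                     expanded_transitions(model), model$order, FALSE)
      total <- total + res$loglik + ed$logshift
    }
  }
  total
}

#' State-posterior decoding
#'
#' Assigns each tile the state with maximal posterior probability
#' `gamma[t, i]`; exact ties go to the lower state index, so decoding is
#' deterministic.
#'
#' @inheritParams forward_backward
#' @return list with `states` (integer indices), `labels` (state labels)
#'   and `posterior` (the posterior of the assigned state per tile).
#' @export
posterior_decode <- function(model, profile) {
  fb <- forward_backward(model, profile)
  idx <- max.col(fb$gamma, ties.method = "first")
  list(states = idx, labels = model$states$labels[idx],
       posterior = fb$gamma[cbind(seq_along(idx), idx)],
       gamma = fb$gamma)
}

#' Sample profiles from a model
#'
#' Ancestral sampling: `q_1 ~ initial`; for 2 <= t <= r the height-(t-1)
#' matrix is applied to the available context; for t > r the height-r
#' matrix; log-ratios are drawn from the state's Gaussian.  All randomness
#' comes from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param model a [phhmm].
#' @param T profile length (tiles), >= 1.
#' @param n number of profiles, >= 1.
#' @param seed optional integer seed.
#' @return list of `n` elements, each `list(values, states)` with `states`
#'   as 1-based state indices.
#' @export
sample_phhmm <- function(model, T, n = 1L, seed = NULL) {
  if (!is.numeric(T) || T < 1 || T != round(T)) {
    stop("T must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  P <- expanded_transitions(model)
  lapply(seq_len(n), function(i) {
    q <- .sample_states_cpp(as.integer(T), unname(model$initial), P,
                            model$order, model$states$K)
    values <- rnorm(T, model$emissions$mean[q], model$emissions$sd[q])
    list(values = values, states = q)
  })
}
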