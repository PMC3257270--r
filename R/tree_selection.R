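#' Optimal leaf probabilities and score for one equivalence class
#'
#' For a leaf with aggregated expected transition counts `n` and aggregated
#' pseudocounts `a`, the penalized expectation-step objective restricted to
#' the leaf is `sum_j (n_j + a_j) log p_j - log Z(a)`.  Its exact maximizer
#' over the simplex is the pseudocount-smoothed frequency
#' `p_j = (n_j + a_j) / sum(n + a)` (no "-1": the Dirichlet is
#' log-space-parameterized), and the score is the objective at the maximum.
#'
#' @param n nonnegative numeric vector of expected counts over next states.
#' @param a strictly positive pseudocounts, same length.
#' @return list with `probs` and `score`.
#' @export
leaf_score <- function(n, a) {
  if (any(a <= 0)) stop("pseudocounts must be strictly positive", call. = FALSE)
  if (any(n < 0)) stop("expected counts must be nonnegative", call. = FALSE)
  w <- n + a
  probs <- w / sum(w)
  list(probs = probs, score = sum(w * log(probs)) - log_dirichlet_z(a))
}

collapse_first <- function(tab, B, K) {
  rest <- nrow(tab) %/% K
  idx0 <- K * (seq_len(rest) - 1L)
  acc <- tab[B[1L] + idx0, , drop = FALSE]
  for (s in B[-1L]) acc <- acc + tab[s + idx0, , drop = FALSE]
  acc
}

#' Select the optimal state-context tree by dynamic programming
#'
#' Maximizes `sum_leaves leaf_score(aggregated counts, aggregated
#' pseudocounts) + kappa * num_leaves` over all set-partition-labeled trees
#' of height k.  The recursion scores a node at depth d with subset path p
#' as its leaf score when d = k, and otherwise as the best over all
#' partitions of the state set of the sum of child values; subtrees are
#' memoized on the subset path, so shared blocks across partitions are
#' solved once.  Ties are broken by the first partition in canonical order,
#' making selection deterministic.
#'
#' @param counts `K^k x K` nonnegative expected transition counts in
#'   context-code row order.
#' @param alpha `K^k x K` strictly positive pseudocounts.
#' @param kappa tree-structure hyper-parameter (per-leaf log-prior weight).
#' @param K number of states.
#' @param k tree height.
#' @param states state labels.
#' @return object of class `tree_score`: list with `tree` (a
#'   `context_tree`), `leaf_probs` (`num_leaves x K`), and `score`.
#' @export
select_optimal_tree <- function(counts, alpha, kappa, K, k,
                                states = default_labels(K)) {
  counts <- as.matrix(counts); alpha <- as.matrix(alpha)
  if (nrow(counts) != K^k || ncol(counts) != K ||
      nrow(alpha) != K^k || ncol(alpha) != K) {
    stop("counts and alpha must be K^k x K", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(alpha <= 0)) stop("pseudocounts must be positive", call. = FALSE)

  parts <- set_partitions(K)
  val <- new.env(parent = emptyenv())
  choice <- new.env(parent = emptyenv())

  solve_node <- function(d, key, tabN, tabA) {
    got <- get0(key, envir = val)
    if (!is.null(got)) return(got)
    if (d == k) {
      v <- leaf_score(as.numeric(tabN), as.numeric(tabA))$score + kappa
    } else {
      best <- -Inf; best_p <- 1L
      for (pi_ in seq_along(parts)) {
        p <- parts[[pi_]]
        tot <- 0
        for (B in p) {
          ck <- paste0(key, ".", sum(2^(B - 1L)))
          tot <- tot + solve_node(d + 1L, ck,
                                  collapse_first(tabN, B, K),
                                  collapse_first(tabA, B, K))
        }
        if (tot > best) {
          best <- tot; best_p <- pi_
        }
      }
      assign(key, best_p, envir = choice)
      v <- best
    }
    assign(key, v, envir = val)
    v
  }
  total <- solve_node(0L, "r", counts, alpha)

  build <- function(d, key) {
    if (d == k) return(NULL)
    p <- parts[[get(key, envir = choice)]]
    list(blocks = p,
         children = lapply(p, function(B) {
           build(d + 1L, paste0(key, ".", sum(2^(B - 1L))))
         }))
  }
  tree <- new_context_tree(build(0L, "r"), K, k, states)

  agg_n <- rowsum(counts, tree$context_map, reorder = TRUE)
  agg_a <- rowsum(alpha, tree$context_map, reorder = TRUE)
  w <- agg_n + agg_a
  probs <- w / rowSums(w)
  rownames(probs) <- tree$leaf_ids
  colnames(probs) <- states

  structure(list(tree = tree, leaf_probs = probs, score = total),
            class = "tree_score")
}

#' Penalized objective of a fixed tree
#'
#' Evaluates `sum_leaves leaf_score + kappa * num_leaves` for a given tree;
#' by construction [select_optimal_tree()] returns a score at least as
#' large for the same inputs.
#'
#' @param tree a `context_tree` of height k.
#' @param counts,alpha `K^k x K` tables as in [select_optimal_tree()].
#' @param kappa tree-structure hyper-parameter.
#' @return numeric score.
#' @export
score_tree <- function(tree, counts, alpha, kappa) {
  stopifnot(inherits(tree, "context_tree"))
  counts <- as.matrix(counts); alpha <- as.matrix(alpha)
  if (nrow(counts) != tree$K^tree$height) {
    stop("counts context length must match the tree height", call. = FALSE)
  }
  agg_n <- rowsum(counts, tree$context_map, reorder = TRUE)
  agg_a <- rowsum(alpha, tree$context_map, reorder = TRUE)
  total <- 0
  for (l in seq_len(nrow(agg_n))) {
    total <- total + leaf_score(agg_n[l, ], agg_a[l, ])$score
  }
  total + kappa * num_leaves(tree)
}
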