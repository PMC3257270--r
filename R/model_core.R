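#' @useDynLib phhmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm rgamma runif quantile sd var
#' @importFrom utils read.table write.table head tail
NULL

DEFAULT_STATES <- c("del", "neutral", "amp")

#' State space of a copy-number HMM
#'
#' The default three states model deletions or sequence deviations
#' (`"del"`, log-ratios much smaller than zero), unchanged regions
#' (`"neutral"`, log-ratios near zero) and amplifications (`"amp"`,
#' log-ratios much greater than zero). States are not tied to specific
#' copy numbers; each carries a flexible Gaussian emission density.
#'
#' @param labels character vector of unique state labels, ordered.
#' @return An object of class `state_space` with elements `labels` and `K`.
#' @export
state_space <- function(labels = DEFAULT_STATES) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("need at least two states", call. = FALSE)
  if (anyDuplicated(labels)) stop("state labels must be unique", call. = FALSE)
  structure(list(labels = labels, K = length(labels)), class = "state_space")
}

## ---------------------------------------------------------------------------
## Context codes
##
## A state-context of length k is c = (c_1, ..., c_k) with c_1 the most
## recent predecessor q_{t-1} and c_k the earliest q_{t-k}.  Contexts are
## indexed by code = 1 + sum_i (c_i - 1) K^(i-1): position 1 is the lowest
## digit.  All context-indexed tables (counts, pseudocounts, expanded
## transition probabilities) use this row order.
## ---------------------------------------------------------------------------

#' Enumerate all state-contexts of length k
#'
#' Rows are in context-code order (position 1 = most recent predecessor in
#' the lowest digit).
#'
#' @param K number of states.
#' @param k context length.
#' @return integer matrix with `K^k` rows and `k` columns.
#' @export
context_table <- function(K, k) {
  stopifnot(K >= 1, k >= 1)
  m <- as.matrix(expand.grid(rep(list(seq_len(K)), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Code of one context
#' @param context integer vector of state indices, most recent first.
#' @param K number of states.
#' @return integer in `1:K^k`.
#' @export
context_code <- function(context, K) {
  as.integer(1L + sum((context - 1L) * K^(seq_along(context) - 1L)))
}

## ---------------------------------------------------------------------------
## Set partitions (canonical order)
## ---------------------------------------------------------------------------

#' All set partitions of 1..n in canonical order
#'
#' Partitions are generated by restricted growth strings in lexicographic
#' order; blocks within a partition are ordered by smallest element and
#' elements within a block are increasing.  This fixed order is the
#' deterministic tie-break used throughout tree selection.
#'
#' @param n set size (the number of states).
#' @return list of partitions; each partition is a list of integer blocks.
#' @export
set_partitions <- function(n) {
  stopifnot(n >= 1)
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxblk) {
    if (i > n) {
      nb <- max(rgs)
      blocks <- lapply(seq_len(nb), function(b) which(rgs == b))
      out[[length(out) + 1L]] <<- blocks
      return(invisible(NULL))
    }
    for (b in seq_len(maxblk + 1L)) {
      rgs[i] <<- b
      recurse(i + 1L, max(maxblk, b))
    }
  }
  rgs[1L] <- 1L
  recurse(2L, 1L)
  out
}

## ---------------------------------------------------------------------------
## Context trees
##
## A context tree of height k is stored as a nested list of nodes.  Each
## internal node is list(blocks = list of integer vectors partitioning
## 1..K, children = list of child nodes, one per block).  Nodes at depth k
## are leaves, stored as NULL.  Derived fields (leaf paths, the
## context -> leaf map, leaf ids) are computed once at construction.
## ---------------------------------------------------------------------------

new_context_tree <- function(root, K, height, states) {
  K <- as.integer(K)
  height <- as.integer(height)
  leaf_paths <- list()
  collect <- function(node, path) {
    if (is.null(node)) {
      leaf_paths[[length(leaf_paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    blocks <- node$blocks
    covered <- sort(unlist(blocks))
    if (!identical(covered, seq_len(K))) {
      stop("node blocks must partition the state set", call. = FALSE)
    }
    for (i in seq_along(blocks)) {
      collect(node$children[[i]], c(path, list(sort(blocks[[i]]))))
    }
  }
  collect(root, list())
  depths <- vapply(leaf_paths, length, 1L)
  if (!all(depths == height)) stop("all leaves must sit at depth k", call. = FALSE)

  ctab <- context_table(K, height)
  map <- integer(nrow(ctab))
  for (l in seq_along(leaf_paths)) {
    sel <- rep(TRUE, nrow(ctab))
    for (pos in seq_len(height)) {
      sel <- sel & (ctab[, pos] %in% leaf_paths[[l]][[pos]])
    }
    map[sel] <- l
  }
  if (any(map == 0L)) stop("context tree does not cover all contexts", call. = FALSE)

  ids <- vapply(leaf_paths, function(p) {
    paste(vapply(p, function(b) paste(sort(states[b]), collapse = ","), ""),
          collapse = "|")
  }, "")

  structure(list(height = height, K = K, states = states, root = root,
                 leaf_paths = leaf_paths, context_map = map,
                 n_leaves = length(leaf_paths), leaf_ids = ids),
            class = "context_tree")
}

#' Number of leaves of a context tree
#' @param tree a `context_tree`.
#' @return integer leaf count (the model complexity of the tree).
#' @export
num_leaves <- function(tree) {
  stopifnot(inherits(tree, "context_tree"))
  tree$n_leaves
}

#' Number of free transition parameters implied by a tree
#'
#' Each leaf carries one probability vector over the K next states, so a
#' tree with L leaves parameterizes `L * K` transition probabilities
#' (e.g. 14 leaves over 3 states give 42; the complete order-4 tree over
#' 3 states has 81 leaves and 243).
#'
#' @param tree a `context_tree`.
#' @param K number of states.
#' @return integer.
#' @export
num_transition_params <- function(tree, K = tree$K) {
  num_leaves(tree) * as.integer(K)
}

complete_node <- function(K, depth) {
  if (depth == 0L) return(NULL)
  list(blocks = lapply(seq_len(K), identity),
       children = lapply(seq_len(K), function(i) complete_node(K, depth - 1L)))
}

fused_node <- function(K, depth) {
  if (depth == 0L) return(NULL)
  list(blocks = list(seq_len(K)),
       children = list(fused_node(K, depth - 1L)))
}

#' Complete state-context tree
#'
#' Every node splits into singleton blocks, so every length-k context has
#' its own leaf: `K^k` leaves.  This is the transition structure of a full
#' order-k HMM.
#'
#' @param K number of states (>= 2).
#' @param k tree height / context length (>= 1).
#' @param states optional state labels (for leaf ids).
#' @return a `context_tree`.
#' @export
build_complete_tree <- function(K, k, states = default_labels(K)) {
  check_tree_args(K, k)
  new_context_tree(complete_node(K, k), K, k, states)
}

#' Fully fused state-context tree
#'
#' Every node carries the single-block partition, so all contexts share one
#' leaf.  An HMM whose transition trees are all fused ignores the state
#' history entirely: its transition process collapses to a mixture model.
#'
#' @inheritParams build_complete_tree
#' @return a `context_tree` with exactly one leaf.
#' @export
build_fused_tree <- function(K, k, states = default_labels(K)) {
  check_tree_args(K, k)
  new_context_tree(fused_node(K, k), K, k, states)
}

check_tree_args <- function(K, k) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K)) {
    stop("K must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  invisible(NULL)
}

default_labels <- function(K) {
  if (K == 3L) DEFAULT_STATES else paste0("s", seq_len(K))
}

#' Resolve a context to its leaf
#'
#' @param tree a `context_tree` of height k.
#' @param context either an integer vector of state indices or a character
#'   vector of state labels, length k, most recent predecessor first.
#' @return the leaf index (integer); its id string is
#'   `tree$leaf_ids[index]`.
#' @export
context_to_leaf <- function(tree, context) {
  stopifnot(inherits(tree, "context_tree"))
  if (is.character(context)) context <- match(context, tree$states)
  if (length(context) != tree$height) {
    stop("context length must equal the tree height", call. = FALSE)
  }
  if (anyNA(context) || any(context < 1L | context > tree$K)) {
    stop("invalid state in context", call. = FALSE)
  }
  tree$context_map[context_code(as.integer(context), tree$K)]
}

#' Enumerate all state-context trees of height k (oracle)
#'
#' Exhaustive, duplicate-free enumeration over the set-partition lattice;
#' intended as a brute-force oracle for validating tree selection on tiny
#' instances.  The number of trees grows super-exponentially in k, so the
#' instance size is guarded.
#'
#' @inheritParams build_complete_tree
#' @param max_trees refuse to enumerate more trees than this.
#' @return list of `context_tree` objects.
#' @export
enumerate_trees <- function(K, k, states = default_labels(K), max_trees = 1000L) {
  check_tree_args(K, k)
  parts <- set_partitions(K)
  n_at <- function(d) {
    if (d == 0L) return(1)
    sum(vapply(parts, function(p) n_at(d - 1L)^length(p), 0))
  }
  if (n_at(k) > max_trees) {
    stop("too many trees to enumerate (", n_at(k), " > ", max_trees, ")",
         call. = FALSE)
  }
  grow <- function(depth) {
    if (depth == 0L) return(list(NULL))
    sub <- grow(depth - 1L)
    out <- list()
    for (p in parts) {
      combos <- expand.grid(rep(list(seq_along(sub)), length(p)),
                            KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(combos))) {
        kids <- lapply(seq_along(p), function(i) sub[[combos[r, i]]])
        out[[length(out) + 1L]] <- list(blocks = p, children = kids)
      }
    }
    out
  }
  lapply(grow(k), new_context_tree, K = K, height = k, states = states)
}

## ---------------------------------------------------------------------------
## Transition matrices and the PHHMM parameter bundle
## ---------------------------------------------------------------------------

#' One tree-structured transition matrix
#'
#' @param tree a `context_tree` of height k.
#' @param probs numeric matrix, `num_leaves(tree)` rows by K columns; each
#'   row a probability vector over next states.
#' @return list with elements `tree` and `probs`, class `phhmm_transitions`.
#' @export
transition_matrix <- function(tree, probs) {
  stopifnot(inherits(tree, "context_tree"))
  probs <- as.matrix(probs)
  if (nrow(probs) != tree$n_leaves || ncol(probs) != tree$K) {
    stop("probs must be num_leaves x K", call. = FALSE)
  }
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-12)) {
    stop("each leaf row must be a probability vector (sum 1 within 1e-12)",
         call. = FALSE)
  }
  rownames(probs) <- tree$leaf_ids
  colnames(probs) <- tree$states
  structure(list(tree = tree, probs = probs), class = "phhmm_transitions")
}

#' Expand a tree-structured matrix to per-context rows
#' @param tm a `phhmm_transitions`.
#' @return `K^k` by K matrix in context-code row order.
#' @export
context_probs <- function(tm) {
  stopifnot(inherits(tm, "phhmm_transitions"))
  unname(tm$probs[tm$tree$context_map, , drop = FALSE])
}

#' Construct a parsimonious higher-order HMM
#'
#' The full parameter bundle: initial state distribution, one
#' tree-structured transition matrix per order 1..r, and per-state Gaussian
#' emission densities on the log-ratio scale.  The matrix of height k is
#' used for the transition into position t = k + 1 (contexts shorter than r
#' exist only at the start of a profile); from position r + 1 on, the
#' height-r matrix applies.  Order 0 is the Gaussian mixture model:
#' positions are independent and `initial` acts as the mixture weights at
#' every position.
#'
#' @param states `state_space` or character vector of labels.
#' @param order model order r >= 0.
#' @param initial numeric probability vector of length K.
#' @param transitions list of `phhmm_transitions`, one per k = 1..r, with
#'   heights 1..r; empty list for order 0.
#' @param mean,sd per-state Gaussian emission parameters (log-ratio units);
#'   all `sd` strictly positive.
#' @return object of class `phhmm`.
#' @export
phhmm <- function(states = DEFAULT_STATES, order, initial, transitions, mean, sd) {
  if (!inherits(states, "state_space")) states <- state_space(states)
  K <- states$K
  if (order < 0 || order != round(order)) stop("order must be >= 0", call. = FALSE)
  initial <- as.numeric(initial)
  if (length(initial) != K || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-12) {
    stop("initial must be a length-K probability vector", call. = FALSE)
  }
  if (order == 0L) {
    transitions <- list()
  } else {
    if (length(transitions) != order) {
      stop("need one transition matrix per order 1..r", call. = FALSE)
    }
    for (k in seq_len(order)) {
      tm <- transitions[[k]]
      if (!inherits(tm, "phhmm_transitions") || tm$tree$height != k) {
        stop("transition matrix ", k, " must have tree height ", k,
             call. = FALSE)
      }
    }
  }
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != K || length(sd) != K || any(!is.finite(mean)) ||
      any(!is.finite(sd)) || any(sd <= 0)) {
    stop("emission mean/sd must be length K with sd > 0", call. = FALSE)
  }
  names(mean) <- names(sd) <- states$labels
  structure(list(states = states, order = as.integer(order),
                 initial = stats::setNames(initial, states$labels),
                 transitions = transitions,
                 emissions = list(mean = mean, sd = sd)),
            class = "phhmm")
}

#' @export
print.phhmm <- function(x, ...) {
  cat("Parsimonious higher-order HMM\n")
  cat("  states:", paste(x$states$labels, collapse = ", "), "\n")
  cat("  order :", x$order, "\n")
  if (x$order > 0L) {
    lv <- vapply(x$transitions, function(tm) tm$tree$n_leaves, 1L)
    cat("  tree leaves by height:", paste(lv, collapse = ", "), "\n")
  }
  cat("  emission means:",
      paste(sprintf("%s=%.3f", x$states$labels, x$emissions$mean),
            collapse = ", "), "\n")
  invisible(x)
}

#' Ordered per-chromosome Array-CGH profile
#'
#' Tiles are 0-based half-open intervals in increasing, non-overlapping
#' order along one chromosome, each carrying a log-ratio.
#'
#' @param chrom chromosome identifier.
#' @param start,end integer tile coordinates (0-based half-open).
#' @param value numeric log-ratios, no missing values.
#' @return object of class `cgh_profile`.
#' @export
cgh_profile <- function(chrom, start, end, value) {
  start <- as.integer(start); end <- as.integer(end)
  value <- as.numeric(value)
  n <- length(value)
  if (n < 1L) stop("a profile needs at least one tile", call. = FALSE)
  if (length(start) != n || length(end) != n) {
    stop("start, end and value lengths differ", call. = FALSE)
  }
  if (anyNA(start) || anyNA(end) || anyNA(value)) {
    stop("missing values are not allowed in a profile", call. = FALSE)
  }
  if (any(end <= start)) stop("tiles must have positive length", call. = FALSE)
  if (n > 1L && any(diff(start) <= 0)) {
    stop("tiles must be strictly increasing by start", call. = FALSE)
  }
  if (n > 1L && any(start[-1L] < end[-n])) {
    stop("tiles must not overlap", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom)[1L], start = start, end = end,
                 value = value), class = "cgh_profile")
}

#' @export
length.cgh_profile <- function(x) length(x$value)

#' @export
print.cgh_profile <- function(x, ...) {
  cat(sprintf("Array-CGH profile %s: %d tiles, [%d, %d)\n", x$chrom,
              length(x$value), x$start[1L], x$end[length(x$end)]))
  invisible(x)
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "cgh_profile")) return(list(profiles))
  if (!is.list(profiles) || length(profiles) == 0L ||
      !all(vapply(profiles, inherits, TRUE, "cgh_profile"))) {
    stop("profiles must be a non-empty list of cgh_profile objects",
         call. = FALSE)
  }
  profiles
}
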