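## Array-CGH-like fixtures with exact ground truth.  Tile geometry follows
## typical tiling-array designs: ~60 bp tiles laid out at ~350 bp spacing
## along each chromosome.

state_runs_to_intervals <- function(profile, states, labels,
                                    neutral = "neutral") {
  lab <- labels[states]
  r <- rle(lab)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values != neutral
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0)))
  }
  data.frame(chrom = profile$chrom,
             start = profile$start[starts_idx[keep]],
             end = profile$end[ends_idx[keep]],
             class = r$values[keep])
}

new_synthetic_dataset <- function(profiles, true_states, generator_spec,
                                  labels, neutral = "neutral") {
  truth <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    state_runs_to_intervals(profiles[[i]], true_states[[i]], labels, neutral)
  }))
  rownames(truth) <- NULL
  structure(list(profiles = profiles, true_states = true_states,
                 truth_intervals = truth, generator_spec = generator_spec),
            class = "cgh_synthetic")
}

#' @export
print.cgh_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic Array-CGH dataset: %d profiles, %d tiles, %d truth intervals\n",
              length(x$profiles),
              sum(vapply(x$profiles, function(p) length(p$value), 1L)),
              nrow(x$truth_intervals)))
  invisible(x)
}

tile_coords <- function(n, tile_length, spacing) {
  start <- as.integer((seq_len(n) - 1L) * spacing)
  list(start = start, end = start + as.integer(tile_length))
}

#' Sample a synthetic dataset from a model
#'
#' Ancestral sampling from a [phhmm] with tile coordinates laid out at
#' fixed spacing; truth intervals are the maximal runs of non-neutral
#' states converted to coordinates.  Regeneration from `generator_spec`
#' (same parameters and seed) is bit-identical.
#'
#' @param model a [phhmm].
#' @param n_chromosomes number of profiles.
#' @param tiles_per_chromosome tiles per profile.
#' @param tile_length tile width in bp (default 60).
#' @param spacing distance between tile starts in bp (default 350).
#' @param seed integer seed.
#' @return object of class `cgh_synthetic`.
#' @export
generate_from_model <- function(model, n_chromosomes, tiles_per_chromosome,
                                tile_length = 60L, spacing = 350L, seed = 1L) {
  if (n_chromosomes < 1 || tiles_per_chromosome < 1 || tile_length < 1 ||
      spacing < tile_length) {
    stop("invalid geometry", call. = FALSE)
  }
  sims <- sample_phhmm(model, T = tiles_per_chromosome, n = n_chromosomes,
                       seed = seed)
  co <- tile_coords(tiles_per_chromosome, tile_length, spacing)
  profiles <- lapply(seq_len(n_chromosomes), function(i) {
    cgh_profile(paste0("chr", i), co$start, co$end, sims[[i]]$values)
  })
  states <- lapply(sims, `[[`, "states")
  spec <- list(generator = "model", n_chromosomes = n_chromosomes,
               tiles_per_chromosome = tiles_per_chromosome,
               tile_length = tile_length, spacing = spacing, seed = seed,
               order = model$order)
  new_synthetic_dataset(profiles, states, spec, model$states$labels)
}

## place non-overlapping segments of ~geometric length until the target
## tile count is reached (within tolerance)
paint_segments <- function(free, target, mean_len, fixed_length) {
  chosen <- integer(0)
  n_placed <- 0L
  attempts <- 0L
  max_attempts <- 200L + 50L * ceiling(target / max(mean_len, 1))
  while (n_placed < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    len <- if (fixed_length) as.integer(mean_len)
           else 1L + stats::rgeom(1L, 1 / mean_len)
    len <- min(len, target - n_placed)   # never overshoot the target
    if (length(free) == 0L) break
    anchor <- free[sample.int(length(free), 1L)]
    seg <- anchor:min(anchor + len - 1L, max(free))
    seg <- seg[seg %in% free]
    if (length(seg) == 0L) next
    chosen <- c(chosen, seg)
    n_placed <- n_placed + length(seg)
    ## keep one-tile gaps so neighbouring segments stay distinct intervals
    free <- setdiff(free, c(seg, min(seg) - 1L, max(seg) + 1L))
  }
  chosen
}

#' Paint aberrant segments onto neutral profiles
#'
#' Plants non-overlapping deletion and amplification segments with
#' geometric (or fixed) tile lengths at random positions until the target
#' tile fractions are met within a +-10% relative band, then draws
#' log-ratios from the class Gaussians.  Defaults emulate the asymmetric
#' log-ratio mixture typical of inter-accession Array-CGH: a dominant bulk
#' near zero, a minor strongly negative deletion component and a very small
#' positive amplification component.
#'
#' @param n_chromosomes,tiles_per_chromosome dataset geometry.
#' @param deletion_fraction,amplification_fraction target tile fractions in
#'   `[0, 1)`, summing to < 1.
#' @param segment_length_mean mean aberrant segment length in tiles.
#' @param means,sds per-class Gaussian parameters, named `del`, `neutral`,
#'   `amp`.
#' @param tile_length,spacing tile geometry in bp.
#' @param fixed_length use fixed- instead of geometric-length segments.
#' @param seed integer seed.
#' @return `cgh_synthetic`.
#' @export
generate_painted <- function(n_chromosomes, tiles_per_chromosome,
                             deletion_fraction = 0.05,
                             amplification_fraction = 0.002,
                             segment_length_mean = 10,
                             means = c(del = -1.5, neutral = 0, amp = 1),
                             sds = c(del = 0.5, neutral = 0.2, amp = 0.5),
                             tile_length = 60L, spacing = 350L,
                             fixed_length = FALSE, seed = 1L) {
  if (deletion_fraction < 0 || amplification_fraction < 0 ||
      deletion_fraction + amplification_fraction >= 1) {
    stop("fractions must be in [0, 1) and sum to < 1", call. = FALSE)
  }
  if (n_chromosomes < 1 || tiles_per_chromosome < 1) {
    stop("invalid geometry", call. = FALSE)
  }
  set.seed(seed)
  labels <- DEFAULT_STATES
  co <- tile_coords(tiles_per_chromosome, tile_length, spacing)
  profiles <- vector("list", n_chromosomes)
  states <- vector("list", n_chromosomes)
  for (i in seq_len(n_chromosomes)) {
    st <- rep(2L, tiles_per_chromosome)             # neutral
    free <- seq_len(tiles_per_chromosome)
    del_target <- round(deletion_fraction * tiles_per_chromosome)
    amp_target <- round(amplification_fraction * tiles_per_chromosome)
    del_idx <- paint_segments(free, del_target, segment_length_mean,
                              fixed_length)
    st[del_idx] <- 1L
    free <- setdiff(free, c(del_idx, del_idx - 1L, del_idx + 1L))
    amp_idx <- paint_segments(free, amp_target, segment_length_mean,
                              fixed_length)
    st[amp_idx] <- 3L
    values <- rnorm(tiles_per_chromosome, means[labels[st]], sds[labels[st]])
    profiles[[i]] <- cgh_profile(paste0("chr", i), co$start, co$end, values)
    states[[i]] <- st
  }
  total <- n_chromosomes * tiles_per_chromosome
  realized_del <- sum(vapply(states, function(s) sum(s == 1L), 1L)) / total
  realized_amp <- sum(vapply(states, function(s) sum(s == 3L), 1L)) / total
  for (pair in list(c(deletion_fraction, realized_del),
                    c(amplification_fraction, realized_amp))) {
    if (pair[1L] > 0 && abs(pair[2L] - pair[1L]) > 0.1 * pair[1L] + 2 / total) {
      stop(sprintf("could not realize target fraction %.4f (got %.4f)",
                   pair[1L], pair[2L]), call. = FALSE)
    }
  }
  spec <- list(generator = "painted", n_chromosomes = n_chromosomes,
               tiles_per_chromosome = tiles_per_chromosome,
               deletion_fraction = deletion_fraction,
               amplification_fraction = amplification_fraction,
               segment_length_mean = segment_length_mean,
               means = as.list(means), sds = as.list(sds),
               tile_length = tile_length, spacing = spacing,
               fixed_length = fixed_length, seed = seed)
  new_synthetic_dataset(profiles, states, spec, labels)
}

#' Degrade truth intervals into imperfect validation labels
#'
#' Emulates external validation data: interval boundaries are jittered
#' uniformly within `+-jitter_bp` and a random fraction of intervals is
#' dropped; the result is re-merged into a valid interval set.
#'
#' @param truth_intervals data.frame with `chrom`, `start`, `end`.
#' @param jitter_bp maximum absolute boundary shift in bp.
#' @param drop_fraction probability of dropping each interval.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end` (merged, sorted).
#' @export
degrade_labels <- function(truth_intervals, jitter_bp = 0L,
                           drop_fraction = 0, seed = 1L) {
  ti <- as.data.frame(truth_intervals)
  set.seed(seed)
  if (nrow(ti) == 0L) return(ti[, c("chrom", "start", "end")])
  keep <- runif(nrow(ti)) >= drop_fraction
  ti <- ti[keep, , drop = FALSE]
  if (nrow(ti) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  if (jitter_bp > 0) {
    ti$start <- ti$start + sample(seq(-jitter_bp, jitter_bp), nrow(ti),
                                  replace = TRUE)
    ti$end <- ti$end + sample(seq(-jitter_bp, jitter_bp), nrow(ti),
                              replace = TRUE)
    ti$start <- pmax(0L, as.integer(ti$start))
    ti$end <- as.integer(pmax(ti$end, ti$start + 1L))
  }
  merge_intervals(ti[, c("chrom", "start", "end")])
}

## merge overlapping intervals per chromosome (0-based half-open)
merge_intervals <- function(regions) {
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) return(regions)
  out <- lapply(split(regions, regions$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1L], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
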