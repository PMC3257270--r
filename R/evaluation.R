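#' Partial autocorrelation of a series
#'
#' Standard Yule-Walker / Durbin-Levinson partial autocorrelation (via
#' `stats::pacf`); the value at lag 1 equals the lag-1 autocorrelation.
#'
#' @param x numeric series (a profile's log-ratios), length > max_lag + 1.
#' @param max_lag largest lag (in tile steps).
#' @return object of class `pacf_result`: list with `lags`, `values`,
#'   `weights` (series length).
#' @export
pacf_series <- function(x, max_lag) {
  x <- as.numeric(x)
  if (length(x) <= max_lag + 1L) stop("series too short for max_lag", call. = FALSE)
  if (stats::var(x) == 0) stop("series has zero variance", call. = FALSE)
  v <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  structure(list(lags = seq_len(max_lag), values = v, weights = length(x)),
            class = "pacf_result")
}

#' Length-weighted mean PACF over profiles
#'
#' Per-lag average of per-profile partial autocorrelations, weighted by
#' profile length (in tiles).  The lag axis is in tile steps; multiply by
#' the mean tile spacing for a distance axis in bp.
#'
#' @param profiles profile list (or list of numeric vectors).
#' @param max_lag largest lag.
#' @return `pacf_result` with summed `weights`.
#' @export
weighted_mean_pacf <- function(profiles, max_lag) {
  if (length(profiles) == 0L) stop("need at least one profile", call. = FALSE)
  series <- lapply(profiles, function(p) {
    if (inherits(p, "cgh_profile")) p$value else as.numeric(p)
  })
  pa <- lapply(series, pacf_series, max_lag = max_lag)
  w <- vapply(pa, `[[`, 0, "weights")
  vals <- sapply(pa, `[[`, "values")
  vals <- matrix(vals, nrow = max_lag)
  structure(list(lags = seq_len(max_lag),
                 values = as.numeric(vals %*% (w / sum(w))),
                 weights = sum(w)),
            class = "pacf_result")
}

#' Permutation baseline of the weighted mean PACF
#'
#' Randomly permutes the measurements within each profile and recomputes
#' the weighted mean PACF, repeated `n_permutations` times.  Permutation
#' destroys the spatial dependence, so mean and standard deviation are
#' close to zero at every lag for any input.
#'
#' @inheritParams weighted_mean_pacf
#' @param n_permutations number of repeats (>= 2).
#' @param seed optional integer seed.
#' @return list with `lags`, `mean`, `sd` per lag.
#' @export
permutation_baseline <- function(profiles, max_lag, n_permutations = 100L,
                                 seed = NULL) {
  if (n_permutations < 2L) stop("need at least two permutations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  series <- lapply(profiles, function(p) {
    if (inherits(p, "cgh_profile")) p$value else as.numeric(p)
  })
  reps <- vapply(seq_len(n_permutations), function(i) {
    perm <- lapply(series, sample)
    weighted_mean_pacf(perm, max_lag)$values
  }, numeric(max_lag))
  reps <- matrix(reps, nrow = max_lag)
  list(lags = seq_len(max_lag), mean = rowMeans(reps),
       sd = apply(reps, 1L, sd))
}

#' PACF modeled by an HMM
#'
#' Samples artificial profiles from the model and returns their weighted
#' mean PACF.  An order-0 model (mixture) models no dependence: all lags
#' fall within the sampling null band; sticky higher-order models show
#' strong short-range partial autocorrelation.
#'
#' @param model a [phhmm].
#' @param n_profiles number of sampled profiles.
#' @param length tiles per sampled profile.
#' @param max_lag largest lag.
#' @param seed optional integer seed.
#' @return `pacf_result`.
#' @export
model_pacf <- function(model, n_profiles = 100L, length = 10000L,
                       max_lag = 20L, seed = NULL) {
  sims <- sample_phhmm(model, T = length, n = n_profiles, seed = seed)
  weighted_mean_pacf(lapply(sims, `[[`, "values"), max_lag)
}

#' Label tiles by candidate-region coverage
#'
#' A tile is labeled positive when at least `min_fraction` of its bases are
#' covered by candidate regions (e.g. at least 45 of 60 bp under the
#' default 0.75).  Overlapping candidate intervals are merged before
#' coverage is computed.
#'
#' @param profile a [cgh_profile].
#' @param regions data.frame with `start`, `end` (0-based half-open) and
#'   optionally `chrom` (filtered to the profile's chromosome if present).
#' @param min_fraction minimum covered fraction (default 0.75).
#' @return logical vector, one per tile.
#' @export
label_tiles_by_coverage <- function(profile, regions, min_fraction = 0.75) {
  stopifnot(inherits(profile, "cgh_profile"))
  regions <- as.data.frame(regions)
  if (!all(c("start", "end") %in% names(regions))) {
    stop("regions must have start and end columns", call. = FALSE)
  }
  if (nrow(regions) > 0L && any(regions$end <= regions$start)) {
    stop("malformed interval (end <= start)", call. = FALSE)
  }
  if ("chrom" %in% names(regions)) {
    regions <- regions[regions$chrom == profile$chrom, , drop = FALSE]
  }
  n <- length(profile$value)
  if (nrow(regions) == 0L) return(rep(FALSE, n))
  ## IRanges are 1-based closed; [start, end) -> [start + 1, end]
  reg <- IRanges::reduce(IRanges::IRanges(regions$start + 1L, regions$end))
  tiles <- IRanges::IRanges(profile$start + 1L, profile$end)
  hits <- IRanges::findOverlaps(tiles, reg)
  covered <- numeric(n)
  if (length(hits) > 0L) {
    ov <- IRanges::pintersect(tiles[S4Vectors::queryHits(hits)],
                              reg[S4Vectors::subjectHits(hits)])
    covered_by <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(covered_by))] <- covered_by
  }
  covered / (profile$end - profile$start) >= min_fraction
}

check_ranking <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  labels
}

#' True-positive rate at a fixed false-positive rate
#'
#' Tiles are ranked by decreasing score (e.g. the posterior probability of
#' the deletion state).  Tied scores enter or leave the threshold set
#' atomically; the TPR is reported at the largest threshold set whose FPR
#' does not exceed the target.
#'
#' @param scores numeric scores, larger = more confident positive.
#' @param labels logical (or 0/1) reference labels.
#' @param fpr target false-positive rate in (0, 1).
#' @return TPR in `[0, 1]`.
#' @export
tpr_at_fpr <- function(scores, labels, fpr) {
  labels <- check_ranking(scores, labels)
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)", call. = FALSE)
  rc <- roc_points(scores, labels)
  ok <- rc$fpr <= fpr
  max(rc$tpr[ok])
}

#' ROC step curve over distinct score thresholds
#'
#' One point per distinct threshold (plus the empty set), accumulating tie
#' groups atomically.
#'
#' @inheritParams tpr_at_fpr
#' @return data.frame with `threshold`, `fpr`, `tpr`, starting at
#'   (Inf, 0, 0) and ending at (min score, 1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- check_ranking(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index per tie group
  tp <- cumsum(l)[grp_last]
  fp <- cumsum(!l)[grp_last]
  data.frame(threshold = c(Inf, s[grp_last]),
             fpr = c(0, fp / sum(!labels)),
             tpr = c(0, tp / sum(labels)))
}

#' Area under the ROC curve
#'
#' Trapezoidal area of [roc_points()]; equals the probability that a random
#' positive outscores a random negative, with half credit for ties.
#'
#' @inheritParams tpr_at_fpr
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  rc <- roc_points(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}
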