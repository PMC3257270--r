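## Profile files: tab-delimited chrom, start, end, log_ratio (0-based
## half-open), optional header; one ordered profile per chromosome.

data_error <- function(...) {
  stop(structure(class = c("phhmm_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read Array-CGH profiles from a tab-delimited file
#'
#' Expects columns chrom, start, end, log_ratio (header optional);
#' coordinates 0-based half-open.  Rows of each chromosome must be sorted
#' by start and non-overlapping; violations are reported with their line
#' number.
#'
#' @param path file path.
#' @return list of [cgh_profile], one per chromosome, in order of first
#'   appearance.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) data_error("no such profile file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) data_error(path, ": empty file")
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  has_header <- length(f1) >= 4L && is.na(suppressWarnings(as.numeric(f1[2L])))
  d <- tryCatch(
    read.table(path, sep = "\t", header = has_header,
               col.names = c("chrom", "start", "end", "log_ratio"),
               colClasses = "character"),
    error = function(e) data_error(path, ": ", conditionMessage(e)))
  if (nrow(d) == 0L) data_error(path, ": no data rows")
  line0 <- as.integer(has_header)
  for (col in c("start", "end", "log_ratio")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  bad <- which(!is.finite(d$start) | !is.finite(d$end) | !is.finite(d$log_ratio))
  if (length(bad) > 0L) {
    data_error(path, ": non-numeric or missing value at line ",
               bad[1L] + line0)
  }
  out <- list()
  for (chrom in unique(d$chrom)) {
    rows <- which(d$chrom == chrom)
    sub <- d[rows, ]
    if (nrow(sub) > 1L) {
      viol <- which(diff(sub$start) <= 0)
      if (length(viol) > 0L) {
        data_error(path, ": tiles out of order or duplicated at line ",
                   rows[viol[1L] + 1L] + line0, " (chromosome ", chrom, ")")
      }
      ovl <- which(sub$start[-1L] < sub$end[-nrow(sub)])
      if (length(ovl) > 0L) {
        data_error(path, ": overlapping tiles at line ",
                   rows[ovl[1L] + 1L] + line0, " (chromosome ", chrom, ")")
      }
    }
    out[[chrom]] <- cgh_profile(chrom, sub$start, sub$end, sub$log_ratio)
  }
  unname(out)
}

#' Write profiles as a tab-delimited file
#' @param profiles profile list.
#' @param path output path.
#' @param header write a header line (default TRUE).
#' @export
write_profiles <- function(profiles, path, header = TRUE) {
  profiles <- as_profile_list(profiles)
  d <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               log_ratio = p$value)
  }))
  if (header) {
    writeLines("chrom\tstart\tend\tlog_ratio", path)
  } else {
    cat(NULL, file = path)
  }
  write.table(format(d, scientific = FALSE, trim = TRUE, digits = 15),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read candidate regions from BED or GFF
#'
#' BED coordinates are used as-is (0-based half-open); GFF start/end
#' (1-based closed, columns 4 and 5) are converted to 0-based half-open.
#' Intervals are merged per chromosome and sorted.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff"`.
#' @return data.frame with `chrom`, `start`, `end` (merged, 0-based
#'   half-open).
#' @export
read_regions <- function(path, format = c("bed", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) data_error("no such region file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  d <- tryCatch(
    read.table(text = lines[keep], sep = "\t", header = FALSE,
               fill = TRUE, stringsAsFactors = FALSE),
    error = function(e) data_error(path, ": ", conditionMessage(e)))
  if (format == "bed") {
    if (ncol(d) < 3L) data_error(path, ": BED needs >= 3 columns")
    reg <- data.frame(chrom = as.character(d[[1L]]),
                      start = suppressWarnings(as.integer(d[[2L]])),
                      end = suppressWarnings(as.integer(d[[3L]])))
  } else {
    if (ncol(d) < 5L) data_error(path, ": GFF needs >= 5 columns")
    reg <- data.frame(chrom = as.character(d[[1L]]),
                      start = suppressWarnings(as.integer(d[[4L]])) - 1L,
                      end = suppressWarnings(as.integer(d[[5L]])))
  }
  if (anyNA(reg$start) || anyNA(reg$end)) {
    data_error(path, ": non-integer coordinates")
  }
  if (any(reg$end <= reg$start)) {
    data_error(path, ": interval with end <= start")
  }
  merge_intervals(reg)
}

#' Write a state-posterior decoding as BED
#'
#' BED6-style rows: chrom, start, end, state label, score (1000 x posterior
#' of the assigned state, rounded), strand ".".  With `merge = TRUE`,
#' adjacent same-state tiles are collapsed into segments scored by their
#' mean posterior.
#'
#' @param profiles profile list.
#' @param decodings list of [posterior_decode()] results aligned with
#'   `profiles`.
#' @param path output path.
#' @param merge collapse same-state runs into segments.
#' @export
write_decoding <- function(profiles, decodings, path, merge = FALSE) {
  profiles <- as_profile_list(profiles)
  if (length(decodings) != length(profiles)) {
    stop("one decoding per profile required", call. = FALSE)
  }
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]; dec <- decodings[[i]]
    if (length(dec$labels) != length(p$value)) {
      stop("decoding ", i, " is not aligned with its profile", call. = FALSE)
    }
    if (merge) {
      r <- rle(dec$labels)
      e_idx <- cumsum(r$lengths)
      s_idx <- e_idx - r$lengths + 1L
      post <- vapply(seq_along(s_idx), function(j) {
        mean(dec$posterior[s_idx[j]:e_idx[j]])
      }, 0)
      data.frame(chrom = p$chrom, start = p$start[s_idx], end = p$end[e_idx],
                 name = r$values, score = round(1000 * post), strand = ".")
    } else {
      data.frame(chrom = p$chrom, start = p$start, end = p$end,
                 name = dec$labels, score = round(1000 * dec$posterior),
                 strand = ".")
    }
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## JSON serialization of trees and models
##
## Tree schema: {"height": k, "states": [...], "root": node} with
## node = {"partition": [[state labels] ...], "children": [node-or-"leaf"]}.
## Model schema adds initial, emissions and per-height leaf probabilities
## keyed by the canonical leaf id.
## ---------------------------------------------------------------------------

tree_to_list <- function(tree) {
  node_to_list <- function(node) {
    if (is.null(node)) return("leaf")
    list(partition = lapply(node$blocks, function(B) sort(tree$states[B])),
         children = lapply(node$children, node_to_list))
  }
  list(height = tree$height, states = as.list(tree$states),
       root = node_to_list(tree$root))
}

tree_from_list <- function(x) {
  states <- unlist(x$states)
  node_from_list <- function(nd) {
    if (identical(nd, "leaf") || identical(nd, list("leaf"))) return(NULL)
    blocks <- lapply(nd$partition, function(lbl) {
      sort(match(unlist(lbl), states))
    })
    list(blocks = blocks, children = lapply(nd$children, node_from_list))
  }
  new_context_tree(node_from_list(x$root), length(states),
                   as.integer(x$height), states)
}

#' Serialize a context tree to JSON
#' @param tree a `context_tree`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return the path, or the JSON string when `path` is `NULL`.
#' @export
write_tree_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(tree_to_list(tree), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a context tree from JSON
#' @param path file path or JSON string.
#' @return a `context_tree`.
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tree_from_list(x)
}

#' Serialize a model to JSON
#' @param model a [phhmm].
#' @param path optional output path.
#' @return the path, or the JSON string when `path` is `NULL`.
#' @export
write_model_json <- function(model, path = NULL) {
  tr <- lapply(model$transitions, function(tm) {
    x <- tree_to_list(tm$tree)
    x$leaf_probs <- stats::setNames(
      lapply(seq_len(nrow(tm$probs)), function(l) as.numeric(tm$probs[l, ])),
      rownames(tm$probs))
    x
  })
  obj <- list(format = "phhmm-model", version = 1L,
              states = as.list(model$states$labels), order = model$order,
              initial = as.numeric(model$initial),
              emissions = list(mean = as.numeric(model$emissions$mean),
                               sd = as.numeric(model$emissions$sd)),
              transitions = tr)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a model from JSON
#' @param path file path or JSON string.
#' @return a [phhmm].
#' @export
read_model_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$format, "phhmm-model")) {
    data_error("not a phhmm model file")
  }
  states <- unlist(x$states)
  transitions <- lapply(x$transitions, function(tx) {
    tree <- tree_from_list(list(height = tx$height, states = as.list(states),
                                root = tx$root))
    probs <- do.call(rbind, lapply(tree$leaf_ids, function(id) {
      as.numeric(unlist(tx$leaf_probs[[id]]))
    }))
    ## renormalize against JSON round-off
    probs <- probs / rowSums(probs)
    transition_matrix(tree, probs)
  })
  phhmm(states = states, order = as.integer(x$order),
        initial = unlist(x$initial), transitions = transitions,
        mean = unlist(x$emissions$mean), sd = unlist(x$emissions$sd))
}
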