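#' Locate initiation events on a combed fiber
#'
#' Two origin signatures are scored. (1) An IdU-containing track flanked on
#' both sides by CldU tracks within the same labeled block: an origin that
#' fired before or during the first pulse; the event sits at the IdU-track
#' midpoint. (2) An interior CldU-only track — a single CldU run forming its
#' own block, bounded away from both fiber ends and no longer than
#' `cldu_only_max_kb`: an origin that fired during the second pulse (an
#' ongoing fork that existed during pulse 1 would carry IdU at one end, so a
#' lone interior CldU patch can only come from a new initiation); the event
#' sits at its midpoint. CldU-only tracks clipped by a fiber end stay
#' ambiguous and are not scored as events. Blocks are maximal runs of
#' labeled segments separated by gaps no wider than `gap_tol`.
#'
#' @param segments Data frame of one fiber's segments (`label`, `start_kb`,
#'   `end_kb`), ordered and disjoint.
#' @param fiber_length Fiber length in kb; `NULL` disables the CldU-only
#'   signature (interiority cannot be judged).
#' @param gap_tol Maximum gap (kb) bridged inside one labeled block.
#' @param cldu_only_max_kb Longest CldU-only track still scored as a
#'   second-pulse initiation (longer tracks cannot arise from two forks in
#'   one pulse at plausible fork speeds).
#' @param edge_tol Distance (kb) from a fiber end below which a track counts
#'   as clipped.
#' @return Numeric vector of event positions (kb, fiber-local), ordered.
#' @export
#' @examples
#' seg <- data.frame(label = c("CldU", "IdU", "CldU"),
#'                   start_kb = c(0, 30, 60), end_kb = c(30, 60, 90))
#' find_initiation_events(seg)  # 45
find_initiation_events <- function(segments, fiber_length = NULL,
                                   gap_tol = 1, cldu_only_max_kb = 100,
                                   edge_tol = 1e-6) {
  runs <- label_runs(segments, gap_tol)
  if (nrow(runs) == 0L) return(numeric(0))
  events <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    if (runs$label[i] == "IdU") {
      has_left <- i > 1 && runs$block[i - 1] == runs$block[i] &&
        runs$label[i - 1] == "CldU"
      has_right <- i < nrow(runs) && runs$block[i + 1] == runs$block[i] &&
        runs$label[i + 1] == "CldU"
      if (has_left && has_right) {
        events <- c(events, (runs$start[i] + runs$end[i]) / 2)
      }
    } else if (!is.null(fiber_length)) {
      alone <- sum(runs$block == runs$block[i]) == 1L
      interior <- runs$start[i] > edge_tol &&
        runs$end[i] < fiber_length - edge_tol
      if (alone && interior &&
          runs$end[i] - runs$start[i] <= cldu_only_max_kb) {
        events <- c(events, (runs$start[i] + runs$end[i]) / 2)
      }
    }
  }
  sort(events)
}

# collapse a fiber's segments into label runs grouped into blocks
label_runs <- function(segments, gap_tol = 1) {
  segments <- segments[segments$label %in% c("IdU", "CldU"), , drop = FALSE]
  if (nrow(segments) == 0L) {
    return(data.frame(label = character(), start = numeric(),
                      end = numeric(), block = integer(),
                      stringsAsFactors = FALSE))
  }
  segments <- segments[order(segments$start_kb), , drop = FALSE]
  lab <- segments$label
  s <- segments$start_kb
  e <- segments$end_kb
  # merge same-label segments separated by <= gap_tol into runs
  runs <- data.frame(label = lab[1], start = s[1], end = e[1],
                     stringsAsFactors = FALSE)
  if (nrow(segments) > 1) {
    for (i in 2:nrow(segments)) {
      j <- nrow(runs)
      if (lab[i] == runs$label[j] && s[i] - runs$end[j] <= gap_tol) {
        runs$end[j] <- max(runs$end[j], e[i])
      } else {
        runs <- rbind(runs, data.frame(label = lab[i], start = s[i],
                                       end = e[i], stringsAsFactors = FALSE))
      }
    }
  }
  gap_prev <- c(Inf, runs$start[-1] - runs$end[-nrow(runs)])
  runs$block <- cumsum(gap_prev > gap_tol)
  runs
}

#' Replication fork velocity from CldU track lengths
#'
#' Measures one velocity per CldU track that is adjacent to an IdU track on
#' exactly one side — an ongoing fork labeled through the whole second
#' pulse. CldU-only tracks (forks born during pulse 2) are excluded, as are
#' CldU tracks flanked by IdU on both sides (terminations, where two forks'
#' tracks have fused) and tracks clipped by a fiber end. Velocity is track
#' length divided by the second-pulse duration.
#'
#' @param fibers A `fiber_set`.
#' @param pulse2_minutes Duration of the CldU pulse, minutes.
#' @param gap_tol Block-joining gap tolerance, kb.
#' @param edge_tol Tracks within this distance of a fiber end are treated as
#'   clipped and skipped, kb.
#' @return Data frame of `fork_measurement`s: `fiber_id`, `velocity`
#'   (kb/min), `track_length` (kb), `label_used`.
#' @export
fork_velocity <- function(fibers, pulse2_minutes = 30, gap_tol = 1,
                          edge_tol = 1e-6) {
  if (pulse2_minutes <= 0) {
    stop("fork_velocity: pulse2_minutes must be positive", call. = FALSE)
  }
  out <- per_fiber(fibers, function(id, len, seg) {
    runs <- label_runs(seg, gap_tol)
    if (nrow(runs) == 0L) return(NULL)
    keep <- logical(nrow(runs))
    for (i in seq_len(nrow(runs))) {
      if (runs$label[i] != "CldU") next
      left_idu <- i > 1 && runs$block[i - 1] == runs$block[i] &&
        runs$label[i - 1] == "IdU"
      right_idu <- i < nrow(runs) && runs$block[i + 1] == runs$block[i] &&
        runs$label[i + 1] == "IdU"
      at_edge <- runs$start[i] <= edge_tol || runs$end[i] >= len - edge_tol
      keep[i] <- xor(left_idu, right_idu) && !at_edge
    }
    if (!any(keep)) return(NULL)
    data.frame(fiber_id = id,
               velocity = (runs$end[keep] - runs$start[keep]) / pulse2_minutes,
               track_length = runs$end[keep] - runs$start[keep],
               label_used = "CldU",
               stringsAsFactors = FALSE)
  })
  if (is.null(out)) {
    out <- data.frame(fiber_id = character(), velocity = numeric(),
                      track_length = numeric(), label_used = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Inter-origin distances
#'
#' Distances between consecutive initiation events on the same fiber; never
#' measured across fibers. The count of distances exceeding 300 kb — a
#' signature of large unfired-origin gaps — is attached as attribute
#' `n_over_300`.
#'
#' @param fibers A `fiber_set`.
#' @param ... Passed to [find_initiation_events()].
#' @return Data frame `fiber_id`, `distance` (kb), with attribute
#'   `n_over_300`.
#' @export
inter_origin_distances <- function(fibers, ...) {
  out <- per_fiber(fibers, function(id, len, seg) {
    ev <- find_initiation_events(seg, fiber_length = len, ...)
    if (length(ev) < 2) return(NULL)
    data.frame(fiber_id = id, distance = diff(ev), stringsAsFactors = FALSE)
  })
  if (is.null(out)) {
    out <- data.frame(fiber_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_over_300") <- sum(out$distance > 300)
  out
}

#' Classify replication figures into five classes
#'
#' Scores every replication structure on every fiber into exactly one of
#' five classes: `isolated_fork` (a labeled track group with no initiation
#' event — a lone fork, including old forks whose origin-proximal DNA is
#' unlabeled), `one_origin_bidirectional` (a single initiation event whose
#' figure lies fully inside the fiber, both outgoing forks visible),
#' `single_origin_only` (a single initiation event whose figure is truncated
#' by a fiber end), `interspersed_origins` (two or more initiation events on
#' one fiber, scored as one structure), and `termination` (a CldU track
#' flanked by IdU on both sides — converging forks that met and fused).
#'
#' @param fibers A `fiber_set`.
#' @param gap_tol Block-joining gap tolerance, kb.
#' @param edge_tol Distance (kb) from a fiber end below which a block counts
#'   as truncated.
#' @param max_structures Stop scoring once this many structures have been
#'   counted (whole fibers are always scored, so the total can exceed it by
#'   a few) — the way a bounded number of structures is scored off a slide.
#' @param fiber_order Optional character vector of fiber ids giving the
#'   order in which fibers are scored (e.g. a random order when scoring a
#'   bounded sample); defaults to id order.
#' @return A `figure_class_counts`: named integer vector over the five
#'   classes plus attribute `n_total` (structures scored).
#' @export
classify_figures <- function(fibers, gap_tol = 1, edge_tol = 1e-6,
                             max_structures = Inf, fiber_order = NULL) {
  classes <- c("isolated_fork", "one_origin_bidirectional",
               "single_origin_only", "interspersed_origins", "termination")
  counts <- stats::setNames(integer(5), classes)
  env <- environment()
  if (!inherits(fibers, "fiber_set")) {
    stop("classify_figures: expected a fiber_set", call. = FALSE)
  }
  idx <- split(seq_len(nrow(fibers)), fibers$fiber_id)
  ids <- if (is.null(fiber_order)) names(idx) else fiber_order
  for (id in ids) {
    if (sum(counts) >= max_structures) break
    ix <- idx[[id]]
    if (is.null(ix)) next
    seg <- fibers[ix, , drop = FALSE]
    classify_one_fiber(seg$length_kb[1], seg, gap_tol, edge_tol, env)
  }
  return(structure(counts, n_total = sum(counts),
                   class = "figure_class_counts"))
}

classify_one_fiber <- function(len, seg, gap_tol, edge_tol, env) {
  with(list(), {
    runs <- label_runs(seg, gap_tol)
    if (nrow(runs) == 0L) return(invisible(NULL))
    ev <- find_initiation_events(seg, fiber_length = len, gap_tol = gap_tol,
                                 edge_tol = edge_tol)
    if (length(ev) >= 2) {
      env$counts["interspersed_origins"] <- env$counts["interspersed_origins"] + 1L
      return(invisible(NULL))
    }
    if (length(ev) == 1) {
      # block holding the event: truncated by a fiber end?
      blk <- runs$block[runs$start <= ev[1] & runs$end >= ev[1]][1]
      if (is.na(blk)) blk <- runs$block[which.min(abs((runs$start + runs$end) / 2 - ev[1]))]
      b <- runs[runs$block == blk, , drop = FALSE]
      truncated <- min(b$start) <= edge_tol || max(b$end) >= len - edge_tol
      cls <- if (truncated) "single_origin_only" else "one_origin_bidirectional"
      env$counts[cls] <- env$counts[cls] + 1L
      # leftover blocks elsewhere on the fiber are scored on their own
      other <- runs[runs$block != blk, , drop = FALSE]
      score_eventless_blocks(other, counts_env = env)
      return(invisible(NULL))
    }
    score_eventless_blocks(runs, counts_env = env)
    invisible(NULL)
  })
}

# helper mutating `counts` in the caller: termination vs isolated fork
score_eventless_blocks <- function(runs, counts_env) {
  if (nrow(runs) == 0L) return(invisible(NULL))
  for (b in unique(runs$block)) {
    r <- runs[runs$block == b, , drop = FALSE]
    is_term <- FALSE
    if (nrow(r) >= 3) {
      for (i in 2:(nrow(r) - 1)) {
        if (r$label[i] == "CldU" && r$label[i - 1] == "IdU" &&
            r$label[i + 1] == "IdU") is_term <- TRUE
      }
    }
    cls <- if (is_term) "termination" else "isolated_fork"
    counts_env$counts[cls] <- counts_env$counts[cls] + 1L
  }
  invisible(NULL)
}

#' @export
print.figure_class_counts <- function(x, ...) {
  cat("replication-figure classes (n =", attr(x, "n_total"), "):\n")
  print(unclass(x))
  invisible(x)
}

# apply f(fiber_id, length, segments) over fibers, rbind non-null results
per_fiber <- function(fibers, f) {
  if (!inherits(fibers, "fiber_set")) {
    stop("expected a fiber_set", call. = FALSE)
  }
  if (nrow(fibers) == 0L) return(NULL)
  res <- lapply(split(seq_len(nrow(fibers)), fibers$fiber_id), function(ix) {
    seg <- fibers[ix, , drop = FALSE]
    f(seg$fiber_id[1], seg$length_kb[1], seg)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Box-and-whisker summary (median, 10-90 percentile whiskers)
#'
#' Median and 10th/90th percentiles by linear interpolation (quantile type
#' 7); values strictly outside the whiskers are reported as outliers.
#'
#' @param values Non-empty numeric vector.
#' @return List `median`, `p10`, `p90`, `outliers`, `n`.
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) {
    stop("box_summary: no finite values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  list(median = q[2], p10 = q[1], p90 = q[3],
       outliers = values[values < q[1] | values > q[3]],
       n = length(values))
}
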