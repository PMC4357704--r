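#' Fiber-set container
#'
#' A fiber set holds single-molecule DNA fibers carrying ordered, disjoint
#' labeled segments from a dual-pulse (IdU then CldU) labeling experiment.
#' The tabular form has one row per segment: `fiber_id`, `length_kb`,
#' `label` (one of `IdU`, `CldU`, `unlabeled`), `start_kb`, `end_kb`, with
#' coordinates local to the fiber.
#'
#' @param df Data frame in the schema above.
#' @return The validated data frame, classed `fiber_set`.
#' @export
fiber_set <- function(df) {
  req <- c("fiber_id", "length_kb", "label", "start_kb", "end_kb")
  if (!all(req %in% names(df))) {
    stop("fiber_set: need columns fiber_id, length_kb, label, start_kb, end_kb",
         call. = FALSE)
  }
  ok_lab <- df$label %in% c("IdU", "CldU", "unlabeled")
  if (!all(ok_lab)) {
    stop(sprintf("fiber_set: invalid label '%s'", df$label[!ok_lab][1]),
         call. = FALSE)
  }
  if (any(df$end_kb <= df$start_kb)) {
    stop("fiber_set: segments must satisfy end_kb > start_kb", call. = FALSE)
  }
  if (any(df$length_kb <= 0)) {
    stop("fiber_set: fiber lengths must be positive", call. = FALSE)
  }
  df <- df[order(df$fiber_id, df$start_kb), , drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$fiber_id)) {
    seg <- df[df$fiber_id == id, , drop = FALSE]
    if (length(unique(seg$length_kb)) != 1L) {
      stop(sprintf("fiber_set: fiber '%s' has inconsistent lengths", id),
           call. = FALSE)
    }
    if (any(seg$start_kb < -1e-9) || any(seg$end_kb > seg$length_kb[1] + 1e-9)) {
      stop(sprintf("fiber_set: fiber '%s' has segments outside [0, length]",
                   id), call. = FALSE)
    }
    if (nrow(seg) > 1 &&
        any(seg$start_kb[-1] < seg$end_kb[-nrow(seg)] - 1e-9)) {
      stop(sprintf("fiber_set: fiber '%s' has overlapping segments", id),
           call. = FALSE)
    }
  }
  class(df) <- c("fiber_set", "data.frame")
  df
}

#' Simulate a dual-pulse DNA combing experiment
#'
#' Simulates an asynchronous cell population: each molecule is one copy of
#' the model chromosome in which every origin fires independently with the
#' condition's probability, at its intrinsic firing time from S-phase start.
#' Two divergent forks leave each fired origin at the genome's fork speed and
#' stop where they meet a converging fork (or a chromosome end). The pulse
#' pair (IdU for `pulse1_minutes`, CldU for `pulse2_minutes`, collection at
#' the end of the second pulse) starts at a uniformly random offset relative
#' to the molecule's S phase, so molecules are caught at every replication
#' stage — as in an unsynchronized culture. DNA replicated during pulse 1 is
#' IdU-labeled, during pulse 2 CldU-labeled, otherwise unlabeled. Molecules
#' are then fragmented into fibers of exponential length, labeled segments
#' shorter than the detection threshold are dropped, and fibers that retain
#' at least one labeled segment are kept until `n_fibers` are collected.
#'
#' @param genome A `genome_model` whose `conditions` contains `condition`.
#' @param condition Name of the firing-probability condition to simulate.
#' @param config A [sim_config()] (pulse durations, fragment length,
#'   detection threshold, fiber count, seed).
#' @param pulse_offset Optional fixed pulse-1 start time (min from S-phase
#'   start) applied to every molecule; `NULL` (default) draws a uniform
#'   offset per molecule. A fixed offset equal to an origin's firing time
#'   reproduces the textbook bidirectional figure exactly.
#' @param max_molecules Safety cap on molecules simulated.
#' @return A `fiber_set`; attribute `fired_positions_kb` lists the fired
#'   origin positions of each simulated molecule (pre-fragmentation truth,
#'   useful for validation).
#' @export
#' @examples
#' g <- make_genome(sim_config(seed = 7), conditions = c(control = 1))
#' f <- make_fibers(g, "control", sim_config(seed = 7, n_fibers = 20))
#' head(f)
make_fibers <- function(genome, condition, config, pulse_offset = NULL,
                        max_molecules = 2000L) {
  if (!inherits(genome, "genome_model")) {
    stop("make_fibers: expected a genome_model", call. = FALSE)
  }
  stopifnot_config(config)
  if (!condition %in% names(genome$conditions)) {
    stop(sprintf("make_fibers: unknown condition '%s'", condition),
         call. = FALSE)
  }
  prob <- genome$conditions[[condition]]
  v <- genome$fork_speed
  p1 <- config$pulse1_minutes
  p2 <- config$pulse2_minutes
  L_kb <- genome$chrom_length / 1000
  set.seed(derive_seed(config$seed, "fibers", condition))

  out <- vector("list", max_molecules)
  fired_list <- vector("list", max_molecules)
  n_kept <- 0L
  mol <- 0L
  next_id <- 1L
  while (n_kept < config$n_fibers && mol < max_molecules) {
    mol <- mol + 1L
    fired <- stats::runif(nrow(genome$origins)) < prob
    fired_list[[mol]] <- genome$origins$position[fired] / 1000
    if (!any(fired)) next
    segs <- molecule_segments(genome$origins$position[fired] / 1000,
                              genome$origins$firing_time[fired],
                              v, L_kb, p1, p2, pulse_offset)
    if (nrow(segs) == 0L) next
    fib <- fragment_molecule(segs, L_kb, config$fiber_length_mean,
                             config$detection_threshold_kb, next_id)
    if (!is.null(fib) && nrow(fib) > 0L) {
      out[[mol]] <- fib
      next_id <- next_id + length(unique(fib$fiber_id_num))
      n_kept <- n_kept + length(unique(fib$fiber_id_num))
    }
  }
  fib <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(fib) || nrow(fib) == 0L) {
    fib <- data.frame(fiber_id = character(), length_kb = numeric(),
                      label = character(), start_kb = numeric(),
                      end_kb = numeric(), stringsAsFactors = FALSE)
    fs <- fiber_set(fib)
    attr(fs, "fired_positions_kb") <- fired_list[seq_len(mol)]
    return(fs)
  }
  if (config$measurement_noise_kb > 0) {
    fib <- jitter_boundaries(fib, config$measurement_noise_kb)
  }
  # trim to exactly n_fibers whole fibers
  ids <- unique(fib$fiber_id_num)
  keep <- ids[seq_len(min(length(ids), config$n_fibers))]
  fib <- fib[fib$fiber_id_num %in% keep, , drop = FALSE]
  fib$fiber_id <- sprintf("fiber_%05d", fib$fiber_id_num)
  fib$fiber_id_num <- NULL
  fs <- fiber_set(fib)
  attr(fs, "fired_positions_kb") <- fired_list[seq_len(mol)]
  fs
}

# Labeled segments of one molecule in chromosome kb coordinates.
# Fired origins (sorted), absolute firing times; pulse1 starts at tau.
molecule_segments <- function(pos_kb, t0, v, L_kb, p1, p2, pulse_offset) {
  ord <- order(pos_kb)
  pos_kb <- pos_kb[ord]
  t0 <- t0[ord]
  n <- length(pos_kb)
  # an origin reached by a neighbouring fork before its own firing time is
  # passively replicated: it adopts the passing fork's arrival time, so the
  # piecewise replication-time envelope stays exact
  t0 <- replication_time_kb(pos_kb, pos_kb, t0, v)
  # fork meeting points between adjacent fired origins (clipped to the gap)
  if (n > 1) {
    meet <- (pos_kb[-n] + pos_kb[-1]) / 2 + v * (t0[-1] - t0[-n]) / 2
    meet <- pmin(pmax(meet, pos_kb[-n]), pos_kb[-1])
  } else {
    meet <- numeric(0)
  }
  left_bound <- c(0, meet)
  right_bound <- c(meet, L_kb)
  # replication end time of the molecule (for the random pulse offset)
  t_finish <- max(t0 + pmax(right_bound - pos_kb, pos_kb - left_bound) / v)
  tau <- if (is.null(pulse_offset)) {
    stats::runif(1, -(p1 + p2), t_finish)
  } else {
    pulse_offset
  }
  seg_s <- numeric(0); seg_e <- numeric(0); seg_l <- character(0)
  windows <- list(IdU = c(tau, tau + p1), CldU = c(tau + p1, tau + p1 + p2))
  for (k in seq_len(n)) {
    for (lab in names(windows)) {
      w <- windows[[lab]]
      # distance range replicated during the window (fork born at t0[k])
      d0 <- v * max(0, w[1] - t0[k])
      d1 <- v * max(0, w[2] - t0[k])
      if (d1 <= d0) next
      # right-moving fork
      s <- min(pos_kb[k] + d0, right_bound[k])
      e <- min(pos_kb[k] + d1, right_bound[k])
      if (e > s) { seg_s <- c(seg_s, s); seg_e <- c(seg_e, e)
                   seg_l <- c(seg_l, lab) }
      # left-moving fork
      s <- max(pos_kb[k] - d1, left_bound[k])
      e <- max(pos_kb[k] - d0, left_bound[k])
      if (e > s) { seg_s <- c(seg_s, s); seg_e <- c(seg_e, e)
                   seg_l <- c(seg_l, lab) }
    }
  }
  if (length(seg_s) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  merge_touching(data.frame(start = seg_s, end = seg_e, label = seg_l,
                            stringsAsFactors = FALSE))
}

# merge same-label segments that touch (forks meeting at origins/junctions)
merge_touching <- function(segs, tol = 1e-9) {
  segs <- segs[order(segs$start), , drop = FALSE]
  out_s <- segs$start[1]; out_e <- segs$end[1]; out_l <- segs$label[1]
  j <- 1L
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      if (segs$label[i] == out_l[j] && segs$start[i] <= out_e[j] + tol) {
        out_e[j] <- max(out_e[j], segs$end[i])
      } else {
        j <- j + 1L
        out_s[j] <- segs$start[i]; out_e[j] <- segs$end[i]
        out_l[j] <- segs$label[i]
      }
    }
  }
  data.frame(start = out_s, end = out_e, label = out_l,
             stringsAsFactors = FALSE)
}

# optical measurement jitter: each distinct segment boundary on a fiber moves
# by one Gaussian draw (shared boundaries move together, order is preserved)
jitter_boundaries <- function(fib, sd_kb) {
  pieces <- lapply(split(seq_len(nrow(fib)), fib$fiber_id_num), function(ix) {
    seg <- fib[ix, , drop = FALSE]
    len <- seg$length_kb[1]
    u <- sort(unique(c(seg$start_kb, seg$end_kb)))
    w <- sort(pmin(pmax(u + stats::rnorm(length(u), 0, sd_kb), 0), len))
    seg$start_kb <- w[match(seg$start_kb, u)]
    seg$end_kb <- w[match(seg$end_kb, u)]
    seg[seg$end_kb > seg$start_kb + 1e-9, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# fragment one molecule into exponential-length fibers; keep labeled fibers
fragment_molecule <- function(segs, L_kb, mean_len, min_seg, id_start) {
  brk <- cumsum(stats::rexp(ceiling(L_kb / mean_len * 3 + 10),
                            rate = 1 / mean_len))
  brk <- brk[brk < L_kb]
  edges <- c(0, brk, L_kb)
  fib_start <- edges[-length(edges)]
  fib_end <- edges[-1]
  rows <- vector("list", length(fib_start))
  kept <- 0L
  for (i in seq_along(fib_start)) {
    s <- pmax(segs$start, fib_start[i])
    e <- pmin(segs$end, fib_end[i])
    sel <- e - s >= min_seg   # detection threshold on the visible piece
    if (!any(sel)) next
    kept <- kept + 1L
    rows[[i]] <- data.frame(
      fiber_id_num = id_start + kept - 1L,
      length_kb = fib_end[i] - fib_start[i],
      label = segs$label[sel],
      start_kb = s[sel] - fib_start[i],
      end_kb = e[sel] - fib_start[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
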