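#' Simulate a chromosome with replication origins
#'
#' Places origins along one chromosome as a Poisson (exponential-spacing)
#' process, groups them into contiguous replication domains (replicon
#' clusters) that activate together, and attaches per-mark fold-enrichments
#' used by [make_chip_track()]. Each domain is early with probability
#' `early_fraction`; its activation time is uniform on the early or late
#' window and its origins fire within `firing_jitter` minutes of activation,
#' so every early origin fires strictly before every late origin while
#' initiation within a cluster stays locally synchronous — the temporal
#' structure that makes inter-origin distances measurable on single fibers.
#'
#' @param config A [sim_config()] object.
#' @param early_fraction Probability that an origin is early-replicating.
#' @param chrom_length Chromosome length in bp.
#' @param chrom_name Chromosome label.
#' @param fork_speed Replication fork speed, kb/min.
#' @param conditions Named numeric vector of per-condition origin-firing
#'   probabilities in \[0, 1\] (per origin, per molecule; all-or-none).
#' @param mark_enrichment Named numeric vector of fold-enrichments (>= 1)
#'   applied at early origins by [make_chip_track()].
#' @param spacing Either `"exponential"` (default; renewal process) or
#'   `"fixed"` for exactly regular spacing (useful for exact-value checks).
#' @param domain_size_kb Replication-domain (replicon-cluster) size, kb.
#'   Origins are grouped into contiguous domains that activate together;
#'   each domain is early with probability `early_fraction`.
#' @param early_window,late_window Domain-activation windows (min from
#'   S-phase start) for early and late domains.
#' @param firing_jitter Within-domain spread of origin firing times, min;
#'   `late_window[1]` must be at least `early_window[2] + firing_jitter` so
#'   every early origin fires strictly before every late origin.
#'
#' @return A `genome_model` list with elements `chrom_name`, `chrom_length`,
#'   `origins` (data frame: `position`, `timing_class`, `firing_time`),
#'   `fork_speed`, `conditions`, `mark_enrichment`.
#' @export
#' @examples
#' g <- make_genome(sim_config(seed = 1), early_fraction = 0.7)
#' head(g$origins)
make_genome <- function(config,
                        early_fraction = 0.7,
                        chrom_length = 10e6,
                        chrom_name = "chrS",
                        fork_speed = 1.5,
                        conditions = c(control = 0.7, knockdown = 0.15),
                        mark_enrichment = c(H3K4me3 = 8, H3K4me2 = 4,
                                            H3K4me1 = 2),
                        spacing = c("exponential", "fixed"),
                        domain_size_kb = 500,
                        early_window = c(0, 25),
                        late_window = c(30, 55),
                        firing_jitter = 4) {
  stopifnot_config(config)
  spacing <- match.arg(spacing)
  if (early_fraction < 0 || early_fraction > 1) {
    stop("make_genome: early_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (chrom_length <= 0 || fork_speed <= 0) {
    stop("make_genome: chrom_length and fork_speed must be positive",
         call. = FALSE)
  }
  if (any(conditions < 0) || any(conditions > 1) || is.null(names(conditions))) {
    stop("make_genome: conditions must be named probabilities in [0, 1]",
         call. = FALSE)
  }
  if (any(mark_enrichment < 1)) {
    stop("make_genome: mark fold-enrichments must be >= 1", call. = FALSE)
  }
  if (late_window[1] < early_window[2] + firing_jitter) {
    stop("make_genome: late domains must activate after every early origin has fired",
         call. = FALSE)
  }

  set.seed(derive_seed(config$seed, "genome"))
  spacing_bp <- config$origin_spacing_mean * 1000
  n_expect <- chrom_length / spacing_bp
  if (spacing == "exponential") {
    # over-draw gaps, then truncate to the chromosome
    gaps <- stats::rexp(ceiling(n_expect + 6 * sqrt(n_expect) + 10),
                        rate = 1 / spacing_bp)
    pos <- cumsum(gaps)
    while (sum(pos) < chrom_length && pos[length(pos)] < chrom_length) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(stats::rexp(10, rate = 1 / spacing_bp)))
    }
    pos <- pos[pos < chrom_length]
  } else {
    pos <- seq(spacing_bp / 2, chrom_length - 1, by = spacing_bp)
  }
  if (length(pos) == 0L) {
    stop("make_genome: no origin fits on the chromosome; increase length",
         call. = FALSE)
  }
  # replicon-cluster temporal program: contiguous domains activate together,
  # origins within a domain fire within `firing_jitter` of the activation time
  dom <- floor(pos / (domain_size_kb * 1000)) + 1L
  n_dom <- max(dom)
  dom_early <- stats::runif(n_dom) < early_fraction
  dom_time <- ifelse(dom_early,
                     stats::runif(n_dom, early_window[1], early_window[2]),
                     stats::runif(n_dom, late_window[1], late_window[2]))
  firing <- dom_time[dom] + stats::runif(length(pos), 0, firing_jitter)
  origins <- data.frame(
    position = pos,
    timing_class = ifelse(dom_early[dom], "early", "late"),
    firing_time = firing,
    domain = dom,
    stringsAsFactors = FALSE
  )
  structure(
    list(chrom_name = chrom_name,
         chrom_length = as.numeric(chrom_length),
         origins = origins,
         fork_speed = as.numeric(fork_speed),
         conditions = conditions,
         mark_enrichment = mark_enrichment),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %s (%.1f Mb), %d origins (%d early), fork %.2f kb/min\n",
              x$chrom_name, x$chrom_length / 1e6, nrow(x$origins),
              sum(x$origins$timing_class == "early"), x$fork_speed))
  invisible(x)
}

#' Replication-timing profile of a simulated genome
#'
#' Computes, for every 1-kb interval, the time at which it replicates when
#' every origin fires (population-average view): the minimum over origins of
#' firing time plus distance over fork speed. Times are rescaled linearly to
#' the 0-100 convention of smoothed Repli-Seq profiles, where the earliest
#' interval maps to 100 and the latest to 0 (higher value = earlier
#' replication).
#'
#' @param genome A `genome_model` from [make_genome()].
#' @param interval_size Interval width in bp.
#' @return A `timing_profile`: data frame `chrom`, `start`, `end`, `value`.
#' @export
make_timing_profile <- function(genome, interval_size = 1000L) {
  if (!inherits(genome, "genome_model")) {
    stop("make_timing_profile: expected a genome_model", call. = FALSE)
  }
  if (nrow(genome$origins) == 0L) {
    stop("make_timing_profile: genome has no origins (unreplicated genome)",
         call. = FALSE)
  }
  starts <- seq(0, genome$chrom_length - 1, by = interval_size)
  ends <- pmin(starts + interval_size, genome$chrom_length)
  mid_kb <- (starts + ends) / 2 / 1000
  t_rep <- replication_time_kb(mid_kb,
                               genome$origins$position / 1000,
                               genome$origins$firing_time,
                               genome$fork_speed)
  rng <- range(t_rep)
  value <- if (rng[2] > rng[1]) {
    100 * (rng[2] - t_rep) / (rng[2] - rng[1])
  } else {
    rep(100, length(t_rep))
  }
  value <- pmin(pmax(value, 0), 100)   # guard fp round-off at the extremes
  timing_profile(data.frame(chrom = genome$chrom_name,
                            start = starts, end = ends,
                            value = value,
                            stringsAsFactors = FALSE))
}

# min over origins of firing_time + |x - p|/v, vectorized over positions (kb).
# Origins must be sorted; uses the nearest-neighbour structure of the min.
replication_time_kb <- function(x_kb, origin_kb, firing_time, fork_speed) {
  ord <- order(origin_kb)
  origin_kb <- origin_kb[ord]
  firing_time <- firing_time[ord]
  n <- length(origin_kb)
  # left-to-right and right-to-left running minima of (t0 - p/v) and (t0 + p/v)
  a <- firing_time - origin_kb / fork_speed   # for origins left of x
  b <- firing_time + origin_kb / fork_speed   # for origins right of x
  a_min <- cummin_left(a)
  b_min <- cummin_right(b)
  idx <- findInterval(x_kb, origin_kb)
  t_left <- ifelse(idx >= 1, a_min[pmax(idx, 1)] + x_kb / fork_speed, Inf)
  t_right <- ifelse(idx < n, b_min[pmin(idx + 1, n)] - x_kb / fork_speed, Inf)
  pmin(t_left, t_right)
}

cummin_left <- function(x) cummin(x)
cummin_right <- function(x) rev(cummin(rev(x)))

#' Simulate a ChIP or input coverage track
#'
#' Draws per-interval read counts with Poisson counting noise around the
#' configured background rate. For a histone mark, intervals within the
#' enrichment window of an early origin have their expectation multiplied by
#' an effective fold `1 + (fold - 1) * knockdown_scale`, where `fold` is the
#' mark's fold-enrichment in the genome model. `mark = "input"` ignores
#' enrichment entirely. `knockdown_scale = 1` is the control condition;
#' values above 1 model a demethylase knockdown that raises the mark, and 0
#' collapses the track onto the input model.
#'
#' @param genome A `genome_model`.
#' @param mark Mark name present in `genome$mark_enrichment`, or `"input"`.
#' @param config A [sim_config()]; `background_rate` sets the unenriched
#'   per-interval expectation and `enrichment_window_kb` the window.
#' @param knockdown_scale Non-negative scaling of the enrichment excess.
#' @return A `coverage_track`: data frame `chrom`, `start`, `end`, `count`
#'   with attribute `library_size` equal to the total reads emitted.
#' @export
make_chip_track <- function(genome, mark, config, knockdown_scale = 1) {
  if (!inherits(genome, "genome_model")) {
    stop("make_chip_track: expected a genome_model", call. = FALSE)
  }
  stopifnot_config(config)
  if (knockdown_scale < 0) {
    stop("make_chip_track: knockdown_scale must be >= 0", call. = FALSE)
  }
  is_input <- identical(mark, "input")
  if (!is_input && !mark %in% names(genome$mark_enrichment)) {
    stop(sprintf("make_chip_track: unknown mark '%s'", mark), call. = FALSE)
  }
  starts <- seq(0, genome$chrom_length - 1, by = config$interval_size)
  ends <- pmin(starts + config$interval_size, genome$chrom_length)
  lambda <- rep(config$background_rate, length(starts))
  if (!is_input) {
    fold <- 1 + (genome$mark_enrichment[[mark]] - 1) * knockdown_scale
    win <- config$enrichment_window_kb * 1000
    early_pos <- genome$origins$position[genome$origins$timing_class == "early"]
    if (length(early_pos) && fold != 1) {
      mids <- (starts + ends) / 2
      enriched <- in_any_window(mids, early_pos, win)
      lambda[enriched] <- lambda[enriched] * fold
    }
  }
  set.seed(derive_seed(config$seed, "chip", mark, knockdown_scale))
  counts <- stats::rpois(length(lambda), lambda)
  coverage_track(data.frame(chrom = genome$chrom_name,
                            start = starts, end = ends,
                            count = counts,
                            stringsAsFactors = FALSE),
                 library_size = sum(counts))
}

# TRUE for positions within +/- win of any center (both in the same unit)
in_any_window <- function(x, centers, win) {
  centers <- sort(centers)
  lo <- findInterval(x, centers - win)
  hi <- findInterval(x, centers + win + .Machine$double.eps)
  lo > hi
}
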