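#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator into one validated
#' object. A fixed `seed` makes every generator deterministic: calling the
#' same generator twice with the same config yields bit-identical output.
#'
#' @param seed Integer seed for the run's RNG stream (mandatory).
#' @param n_fibers Number of labeled fibers to retain from the combing
#'   simulation.
#' @param fiber_length_mean Mean fragment length after molecule breakage, kb.
#' @param origin_spacing_mean Mean distance between consecutive origins, kb
#'   (exponential spacing by default; see [make_genome()]).
#' @param pulse1_minutes Duration of the first (IdU) pulse, minutes.
#' @param pulse2_minutes Duration of the second (CldU) pulse, minutes.
#' @param depth Reserved overall sequencing-depth control (reads); the
#'   per-interval expectation is `background_rate`.
#' @param background_rate Expected reads per 1-kb interval away from any
#'   enriched window.
#' @param interval_size Genomic interval width in bp (1 kb, the resolution of
#'   the smoothed replication-timing profiles consumed downstream).
#' @param detection_threshold_kb Shortest labeled segment that survives on a
#'   combed fiber, kb (combing resolution).
#' @param enrichment_window_kb Half-width of the mark-enrichment window
#'   around early origins, kb.
#' @param ct_noise_sd Gaussian noise SD on simulated qPCR Ct values, cycles.
#' @param measurement_noise_kb SD of the optical measurement jitter applied
#'   to fiber segment boundaries, kb (0 = exact geometry).
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$pulse2_minutes
sim_config <- function(seed,
                       n_fibers = 200L,
                       fiber_length_mean = 600,
                       origin_spacing_mean = 100,
                       pulse1_minutes = 15,
                       pulse2_minutes = 30,
                       depth = 1e5,
                       background_rate = 5,
                       interval_size = 1000L,
                       detection_threshold_kb = 1,
                       enrichment_window_kb = 2,
                       ct_noise_sd = 0.15,
                       measurement_noise_kb = 0) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("sim_config: a single finite integer `seed` is mandatory",
         call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_fibers = as.integer(n_fibers),
    fiber_length_mean = as.numeric(fiber_length_mean),
    origin_spacing_mean = as.numeric(origin_spacing_mean),
    pulse1_minutes = as.numeric(pulse1_minutes),
    pulse2_minutes = as.numeric(pulse2_minutes),
    depth = as.numeric(depth),
    background_rate = as.numeric(background_rate),
    interval_size = as.integer(interval_size),
    detection_threshold_kb = as.numeric(detection_threshold_kb),
    enrichment_window_kb = as.numeric(enrichment_window_kb),
    ct_noise_sd = as.numeric(ct_noise_sd),
    measurement_noise_kb = as.numeric(measurement_noise_kb)
  )
  positive <- c("n_fibers", "fiber_length_mean", "origin_spacing_mean",
                "pulse1_minutes", "pulse2_minutes", "depth",
                "background_rate", "interval_size")
  for (nm in positive) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("sim_config: `%s` must be a positive finite number", nm),
           call. = FALSE)
    }
  }
  if (cfg$detection_threshold_kb < 0 || cfg$enrichment_window_kb < 0 ||
      cfg$ct_noise_sd < 0 || cfg$measurement_noise_kb < 0) {
    stop("sim_config: thresholds and noise SDs must be non-negative",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-call seed: mixes the run seed with a stable string key so
# distinct generator calls (e.g. the H3K4me3 track vs its matched input) get
# independent draws while any one call stays reproducible. Kept below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("expected a `sim_config` object (see sim_config())", call. = FALSE)
  }
  invisible(config)
}
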