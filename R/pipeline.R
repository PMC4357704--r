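#' Run configuration
#'
#' Collects the seed, input paths and analysis parameters of one
#' reproducible pipeline run. Configurations round-trip through YAML with
#' [read_run_config()] / [write_run_config()].
#'
#' @param seed Integer seed (drives every stochastic stage).
#' @param out_dir Output directory (created if missing).
#' @param paths Named list of input paths (e.g. `profile`, `tracks`,
#'   `fibers`, `qpcr`) for stages run on existing files; stages that
#'   simulate their inputs need none.
#' @param n_bins Timing bins. @param n_assumed Assumed KS sample size.
#' @param pulse1_minutes,pulse2_minutes Pulse durations, min.
#' @param detection_threshold_kb Fiber detection threshold, kb.
#' @param input_fraction qPCR input aliquot fraction.
#' @param sim Named list of overrides passed to [sim_config()] for
#'   simulation stages.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, out_dir = "results", paths = list(),
                       n_bins = 100L, n_assumed = 100, pulse1_minutes = 15,
                       pulse2_minutes = 30, detection_threshold_kb = 1,
                       input_fraction = 1, sim = list()) {
  if (missing(seed)) stop("run_config: seed is mandatory", call. = FALSE)
  if (n_bins < 1 || n_assumed < 1 || pulse1_minutes <= 0 ||
      pulse2_minutes <= 0 || input_fraction <= 0 || input_fraction > 1) {
    stop("run_config: parameter outside documented range", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir, paths = paths,
                 n_bins = as.integer(n_bins), n_assumed = n_assumed,
                 pulse1_minutes = pulse1_minutes,
                 pulse2_minutes = pulse2_minutes,
                 detection_threshold_kb = detection_threshold_kb,
                 input_fraction = input_fraction, sim = sim),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_run_config: no such file: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

sim_config_from_run <- function(config) {
  do.call(sim_config, c(list(seed = config$seed), config$sim))
}

#' Run one pipeline stage
#'
#' Executes a named analysis stage with the given configuration, writes its
#' result files under `config$out_dir` and a machine-readable run manifest
#' (`<command>_manifest.json`: command, parameters, package version, input
#' checksums, output checksums) alongside them. Outputs are deterministic
#' for a fixed config; two runs with the same config are byte-identical.
#'
#' Stages: `"simulate"` writes a simulated timing profile (bedGraph),
#' H3K4me3/input coverage (bedGraph) and control/knockdown fiber sets (TSV);
#' `"timing-dist"` computes mark-vs-input timing distributions and the KS
#' report (TSV) from the simulate outputs or `config$paths`; `"combing"`
#' computes fork-velocity / IOD measurements, box summaries and the figure
#' class comparison; `"qpcr"` recovers percent input from a Ct table.
#'
#' @param config A [run_config()].
#' @param command One of `"simulate"`, `"timing-dist"`, `"combing"`,
#'   `"qpcr"`.
#' @return Invisibly, a named list of written file paths. Errors (e.g. a
#'   missing input path, named in the message) propagate as R conditions —
#'   a non-zero exit under `Rscript`.
#' @export
run_pipeline <- function(config, command = c("simulate", "timing-dist",
                                             "combing", "qpcr")) {
  command <- match.arg(command)
  if (!inherits(config, "run_config")) {
    stop("run_pipeline: expected a run_config", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- switch(
    command,
    "simulate" = stage_simulate(config),
    "timing-dist" = {
      inputs <- stage_inputs(config, c("profile", "mark", "input"),
                             c("profile.bedGraph", "H3K4me3.bedGraph",
                               "input.bedGraph"))
      stage_timing_dist(config, inputs)
    },
    "combing" = {
      inputs <- stage_inputs(config, c("fibers_control", "fibers_knockdown"),
                             c("fibers_control.tsv", "fibers_knockdown.tsv"))
      stage_combing(config, inputs)
    },
    "qpcr" = {
      inputs <- stage_inputs(config, "qpcr", "ct_table.csv")
      stage_qpcr(config, inputs)
    }
  )
  manifest <- list(
    command = command,
    package = "oritime",
    version = as.character(utils::packageVersion("oritime")),
    parameters = unclass(config),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unlist(outputs)))
  )
  mpath <- file.path(config$out_dir, paste0(gsub("-", "_", command),
                                            "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(outputs, manifest = mpath))
}

# resolve stage inputs from config$paths or prior simulate outputs
stage_inputs <- function(config, keys, defaults) {
  paths <- vapply(seq_along(keys), function(i) {
    p <- config$paths[[keys[i]]]
    if (is.null(p)) file.path(config$out_dir, defaults[i]) else p
  }, character(1))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("run_pipeline: missing input path(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(paths, keys)
}

stage_simulate <- function(config) {
  scfg <- sim_config_from_run(config)
  genome <- make_genome(scfg)
  out <- list(
    profile = file.path(config$out_dir, "profile.bedGraph"),
    mark = file.path(config$out_dir, "H3K4me3.bedGraph"),
    input = file.path(config$out_dir, "input.bedGraph"),
    fibers_control = file.path(config$out_dir, "fibers_control.tsv"),
    fibers_knockdown = file.path(config$out_dir, "fibers_knockdown.tsv")
  )
  write_bedgraph(make_timing_profile(genome, scfg$interval_size),
                 out$profile)
  write_bedgraph(make_chip_track(genome, "H3K4me3", scfg), out$mark)
  write_bedgraph(make_chip_track(genome, "input", scfg), out$input)
  write_fibers(make_fibers(genome, "control", scfg), out$fibers_control)
  write_fibers(make_fibers(genome, "knockdown", scfg), out$fibers_knockdown)
  out
}

stage_timing_dist <- function(config, inputs) {
  profile <- read_bedgraph(inputs[["profile"]], as = "profile")
  mark <- read_bedgraph(inputs[["mark"]], as = "track")
  input <- read_bedgraph(inputs[["input"]], as = "track")
  dmark <- timing_distribution(mark, profile, config$n_bins)
  dinput <- timing_distribution(input, profile, config$n_bins)
  report <- mark_vs_input_report(list(H3K4me3 = dmark), dinput,
                                 n_assumed = config$n_assumed)
  out <- list(report = file.path(config$out_dir, "ks_report.tsv"),
              bins = file.path(config$out_dir, "timing_bins.tsv"))
  utils::write.table(report, out$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(bin = dmark$bins, H3K4me3 = dmark$density,
               input = dinput$density),
    out$bins, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

stage_combing <- function(config, inputs) {
  ctl <- read_fibers(inputs[["fibers_control"]])
  kd <- read_fibers(inputs[["fibers_knockdown"]])
  vel_c <- fork_velocity(ctl, config$pulse2_minutes)
  vel_k <- fork_velocity(kd, config$pulse2_minutes)
  iod_c <- inter_origin_distances(ctl)
  iod_k <- inter_origin_distances(kd)
  cls_c <- classify_figures(ctl)
  cls_k <- classify_figures(kd)
  stats <- list(
    velocity = c(list(median_control = stats::median(vel_c$velocity),
                      median_knockdown = stats::median(vel_k$velocity),
                      n_control = nrow(vel_c), n_knockdown = nrow(vel_k)),
                 mann_whitney(vel_c$velocity, vel_k$velocity)["p_value"]),
    iod = c(list(median_control = stats::median(iod_c$distance),
                 median_knockdown = stats::median(iod_k$distance),
                 n_control = nrow(iod_c), n_knockdown = nrow(iod_k),
                 over_300_control = attr(iod_c, "n_over_300"),
                 over_300_knockdown = attr(iod_k, "n_over_300")),
            mann_whitney(iod_c$distance, iod_k$distance)["p_value"]),
    figures = chi_square_counts(cls_c, cls_k)[c("statistic", "df", "p_value")],
    box_velocity_control = box_summary(vel_c$velocity)[c("median", "p10", "p90")],
    box_iod_control = box_summary(iod_c$distance)[c("median", "p10", "p90")]
  )
  out <- list(
    velocity = file.path(config$out_dir, "fork_velocity.tsv"),
    iod = file.path(config$out_dir, "iod.tsv"),
    classes = file.path(config$out_dir, "figure_classes.tsv"),
    stats = file.path(config$out_dir, "combing_stats.json")
  )
  vel_c$condition <- "control"; vel_k$condition <- "knockdown"
  utils::write.table(rbind(vel_c, vel_k), out$velocity, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  iod_c$condition <- "control"; iod_k$condition <- "knockdown"
  utils::write.table(rbind(iod_c, iod_k), out$iod, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(class = names(unclass(cls_c)),
               control = as.integer(cls_c), knockdown = as.integer(cls_k)),
    out$classes, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(stats, out$stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out
}

stage_qpcr <- function(config, inputs) {
  tab <- read_ct_table(inputs[["qpcr"]])
  res <- percent_input_table(tab)
  out <- list(percent_input = file.path(config$out_dir, "percent_input.csv"))
  utils::write.csv(res, out$percent_input, row.names = FALSE, quote = FALSE)
  out
}
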