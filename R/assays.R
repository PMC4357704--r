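#' Simulate a ChIP-qPCR Ct table
#'
#' Emits paired IP and input Ct values per amplicon with Gaussian Ct noise,
#' constructed so that the expected recovered percent input equals the true
#' enrichment (the small lognormal bias of exponentiating Gaussian Ct noise
#' is removed analytically). Input Cts are reported for an aliquot of
#' `input_fraction` of the chromatin, the convention [percent_input()]
#' adjusts for.
#'
#' @param amplicons Named numeric vector: true percent-input per amplicon
#'   (e.g. `c(TOP1_ori = 3, TOP1_m5kb = 1)`), all positive.
#' @param config A [sim_config()]; `ct_noise_sd` is the per-Ct Gaussian SD
#'   in cycles (0 gives a noise-free table).
#' @param input_fraction Fraction of chromatin used as the input aliquot.
#' @param base_ct Mean input Ct before dilution adjustment, cycles.
#' @return A `ct_table` data frame: `amplicon`, `role` (`IP`/`input`), `ct`,
#'   `input_fraction`.
#' @export
#' @examples
#' tab <- make_qpcr(c(ori = 2, flank = 0.5),
#'                  sim_config(seed = 3, ct_noise_sd = 0))
#' percent_input_table(tab)
make_qpcr <- function(amplicons, config, input_fraction = 1, base_ct = 25) {
  stopifnot_config(config)
  if (is.null(names(amplicons)) || any(amplicons <= 0)) {
    stop("make_qpcr: amplicons must be a named vector of positive % input",
         call. = FALSE)
  }
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("make_qpcr: input_fraction must be in (0, 1]", call. = FALSE)
  }
  sd <- config$ct_noise_sd
  set.seed(derive_seed(config$seed, "qpcr", paste(names(amplicons),
                                                  collapse = ",")))
  n <- length(amplicons)
  # E[2^(e_in - e_ip)] = exp((log 2)^2 sd^2) for independent N(0, sd) noises;
  # shift ct_ip by log2 of that so the expected % input is exactly the truth
  bias_ct <- (log(2)) * sd^2
  ct_input <- base_ct + stats::rnorm(n, 0, sd)
  dilution <- log2(1 / input_fraction)
  ct_ip <- (base_ct - dilution) - log2(amplicons / 100) + bias_ct +
    stats::rnorm(n, 0, sd)
  out <- data.frame(
    amplicon = rep(names(amplicons), each = 2),
    role = rep(c("IP", "input"), n),
    ct = as.vector(rbind(ct_ip, ct_input)),
    input_fraction = input_fraction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Simulate BrdU flow-cytometry intensities
#'
#' Draws lognormal BrdU fluorescence intensities for an S-phase population
#' (mean `background + net_s_signal`) and a BrdU-negative G1/G2M population
#' (mean `background`), the two populations [relative_brdu()] consumes.
#'
#' @param n_cells Cells per population.
#' @param net_s_signal Net BrdU incorporation signal of S-phase cells.
#' @param background Nonspecific background intensity (both populations).
#' @param config A [sim_config()] (seed).
#' @param cv Coefficient of variation of the lognormal intensities.
#' @return List of intensity vectors `s` and `negative`.
#' @export
make_facs <- function(n_cells, net_s_signal, background, config, cv = 0.4) {
  stopifnot_config(config)
  if (net_s_signal < 0 || background < 0) {
    stop("make_facs: intensities must be non-negative", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "facs", net_s_signal, background))
  draw <- function(mean_int) {
    if (mean_int == 0) return(numeric(n_cells))
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mean_int) - sdlog^2 / 2
    stats::rlnorm(n_cells, meanlog, sdlog)
  }
  list(s = draw(background + net_s_signal), negative = draw(background))
}
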