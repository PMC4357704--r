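#' ChIP-qPCR percent input
#'
#' Converts paired IP/input Ct values to the percent-input enrichment scale:
#' the input Ct is first adjusted for the aliquot dilution
#' (`ct_input - log2(1 / input_fraction)`, i.e. the Ct the full input would
#' have shown), then `% input = 100 * 2^(ct_input_adj - ct_ip)`. Adding a
#' constant to both Cts leaves the result unchanged.
#'
#' @param ct_ip IP Ct, cycles (vectorized).
#' @param ct_input Input-aliquot Ct, cycles.
#' @param input_fraction Fraction of chromatin run as input (default 1 =
#'   Cts already adjusted).
#' @return Percent input (percentage scale; 1 means 1%).
#' @export
#' @examples
#' percent_input(25, 25)            # 100
#' percent_input(26, 25)            # 50
#' percent_input(20, 25, input_fraction = 0.01)  # dilution-adjusted
percent_input <- function(ct_ip, ct_input, input_fraction = 1) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("percent_input: input_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(ct_ip <= 0) || any(ct_input <= 0)) {
    stop("percent_input: Ct values must be positive", call. = FALSE)
  }
  ct_input_adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(ct_input_adj - ct_ip)
}

#' Percent input for every amplicon of a Ct table
#'
#' @param ct_table A `ct_table` (see [make_qpcr()] / [read_ct_table()]).
#' @return Data frame `amplicon`, `percent_input`.
#' @export
percent_input_table <- function(ct_table) {
  need <- c("amplicon", "role", "ct", "input_fraction")
  if (!all(need %in% names(ct_table))) {
    stop("percent_input_table: need columns amplicon, role, ct, input_fraction",
         call. = FALSE)
  }
  ip <- ct_table[ct_table$role == "IP", ]
  inp <- ct_table[ct_table$role == "input", ]
  if (!setequal(ip$amplicon, inp$amplicon)) {
    stop("percent_input_table: every amplicon needs one IP and one input row",
         call. = FALSE)
  }
  inp <- inp[match(ip$amplicon, inp$amplicon), ]
  data.frame(amplicon = ip$amplicon,
             percent_input = percent_input(ip$ct, inp$ct, inp$input_fraction),
             stringsAsFactors = FALSE)
}

#' Origin-versus-flank enrichment profile
#'
#' Summarizes a locus-design qPCR experiment (amplicons at the origin and at
#' flanking positions, e.g. -5 kb / ori / +5 kb) into percent input per
#' amplicon plus the ratio of the origin signal to the mean flank signal per
#' locus. Loci with missing flanks get the ratio over the available flanks
#' and are flagged.
#'
#' @param measurements Data frame with columns `locus`, `position` (one of
#'   them `"ori"` per locus), `ct_ip`, `ct_input` and optionally
#'   `input_fraction`.
#' @return List `amplicons` (locus, position, percent_input) and `loci`
#'   (locus, ori_percent_input, flank_mean, ratio, n_flanks, flagged).
#' @export
origin_flank_profile <- function(measurements) {
  need <- c("locus", "position", "ct_ip", "ct_input")
  if (!all(need %in% names(measurements))) {
    stop("origin_flank_profile: need columns locus, position, ct_ip, ct_input",
         call. = FALSE)
  }
  f <- if ("input_fraction" %in% names(measurements)) {
    measurements$input_fraction
  } else 1
  measurements$percent_input <- percent_input(measurements$ct_ip,
                                              measurements$ct_input, f)
  loci <- lapply(split(measurements, measurements$locus), function(m) {
    ori <- m$percent_input[m$position == "ori"]
    if (length(ori) != 1L) {
      stop(sprintf("origin_flank_profile: locus '%s' needs exactly one 'ori' amplicon",
                   m$locus[1]), call. = FALSE)
    }
    flanks <- m$percent_input[m$position != "ori"]
    data.frame(locus = m$locus[1],
               ori_percent_input = ori,
               flank_mean = if (length(flanks)) mean(flanks) else NA_real_,
               ratio = if (length(flanks)) ori / mean(flanks) else NA_real_,
               n_flanks = length(flanks),
               flagged = length(flanks) < 2,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  list(amplicons = measurements[, c("locus", "position", "percent_input")],
       loci = loci)
}

#' Relative BrdU fluorescence
#'
#' Net BrdU signal of S-phase cells (S-population mean minus the
#' BrdU-negative G1/G2M population mean) normalized to the control
#' condition's net signal. A control condition measured against itself gives
#' 1; a knockdown with half the net signal gives 0.5, i.e. a 2-fold
#' decrease.
#'
#' @param s_mean Mean BrdU intensity of S-phase cells.
#' @param neg_mean Mean intensity of BrdU-negative G1/G2M cells.
#' @param reference_net Net signal (`s_mean - neg_mean`) of the control.
#' @return Relative BrdU fluorescence (unitless ratio).
#' @export
relative_brdu <- function(s_mean, neg_mean, reference_net) {
  if (reference_net <= 0) {
    stop("relative_brdu: reference_net must be positive", call. = FALSE)
  }
  net <- s_mean - neg_mean
  if (net < 0) {
    warning("relative_brdu: negative net signal, returning 0", call. = FALSE)
    return(0)
  }
  net / reference_net
}

#' H3-normalized densitometry
#'
#' Western-blot band density divided by the histone H3 density of the same
#' sample (arbitrary units); invariant to a common exposure scaling.
#'
#' @param band_density Band density, arbitrary units (> 0).
#' @param h3_density H3 loading-control density of the same lane (> 0).
#' @return Ratio in arbitrary units.
#' @export
densitometry_ratio <- function(band_density, h3_density) {
  if (any(band_density <= 0) || any(h3_density <= 0)) {
    stop("densitometry_ratio: densities must be positive", call. = FALSE)
  }
  band_density / h3_density
}
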