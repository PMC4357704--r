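#' Read and write bedGraph tracks
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open.
#' `track` and comment/browser lines are skipped. Overlapping intervals or
#' non-numeric values raise errors naming the offending line. An empty file
#' yields an empty object with a warning.
#'
#' @param path File path.
#' @param as `"profile"` for a [timing_profile()] (values must lie in
#'   \[0, 100\]) or `"track"` for a [coverage_track()] (counts).
#' @param library_size Library size for `as = "track"`; defaults to the
#'   in-interval total.
#' @return A `timing_profile` or `coverage_track`.
#' @export
read_bedgraph <- function(path, as = c("profile", "track"),
                          library_size = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) {
    stop(sprintf("read_bedgraph: no such file: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning(sprintf("read_bedgraph: %s has no data lines", path),
            call. = FALSE)
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), value = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    ln <- which(keep)
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 4)) {
      stop(sprintf("read_bedgraph: line %d does not have 4 fields",
                   ln[which(nf != 4)[1]]), call. = FALSE)
    }
    mat <- do.call(rbind, fields)
    val <- suppressWarnings(as.numeric(mat[, 4]))
    st <- suppressWarnings(as.numeric(mat[, 2]))
    en <- suppressWarnings(as.numeric(mat[, 3]))
    bad <- which(!is.finite(val) | !is.finite(st) | !is.finite(en))
    if (length(bad)) {
      stop(sprintf("read_bedgraph: non-numeric field on line %d", ln[bad[1]]),
           call. = FALSE)
    }
    df <- data.frame(chrom = mat[, 1], start = st, end = en, value = val,
                     stringsAsFactors = FALSE)
  }
  if (as == "profile") {
    timing_profile(df)
  } else {
    names(df)[names(df) == "value"] <- "count"
    if (is.null(library_size)) library_size <- sum(df$count)
    coverage_track(df, library_size = library_size)
  }
}

#' @rdname read_bedgraph
#' @param x A `timing_profile` or `coverage_track` to write.
#' @export
write_bedgraph <- function(x, path) {
  val <- if (inherits(x, "coverage_track")) x$count else x$value
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE), val)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write fiber-set TSVs
#'
#' Tab-separated schema: `fiber_id`, `length_kb`, `label`, `start_kb`,
#' `end_kb` — one row per labeled segment, coordinates local to the fiber.
#' Writing then reading is the identity. Invalid labels or segments outside
#' the fiber raise errors with the line number; rows sharing a `fiber_id`
#' (with disjoint segments) are merged under one fiber.
#'
#' @param path File path.
#' @return A `fiber_set`.
#' @export
read_fibers <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_fibers: no such file: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  bad <- which(!df$label %in% c("IdU", "CldU", "unlabeled"))
  if (length(bad)) {
    stop(sprintf("read_fibers: invalid label '%s' on line %d",
                 df$label[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  out <- df[, c("fiber_id", "length_kb", "label", "start_kb", "end_kb")]
  bad <- which(out$end_kb > out$length_kb + 1e-9 | out$start_kb < -1e-9)
  if (length(bad)) {
    stop(sprintf("read_fibers: segment outside fiber on line %d",
                 bad[1] + 1L), call. = FALSE)
  }
  fiber_set(out)
}

#' @rdname read_fibers
#' @param fibers A `fiber_set` to write.
#' @export
write_fibers <- function(fibers, path) {
  utils::write.table(as.data.frame(fibers)[, c("fiber_id", "length_kb",
                                               "label", "start_kb",
                                               "end_kb")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write qPCR Ct tables
#'
#' CSV schema: `amplicon`, `role` (`IP`/`input`), `ct`, `input_fraction`.
#' The writer prepends a header comment recording the percent-input formula
#' version; the reader skips comments.
#'
#' @param path File path.
#' @return A `ct_table` data frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_ct_table: no such file: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("amplicon", "role", "ct", "input_fraction")
  if (!all(need %in% names(df))) {
    stop("read_ct_table: need columns amplicon, role, ct, input_fraction",
         call. = FALSE)
  }
  if (!all(df$role %in% c("IP", "input"))) {
    stop("read_ct_table: role must be IP or input", call. = FALSE)
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' @rdname read_ct_table
#' @param ct_table A `ct_table` to write.
#' @export
write_ct_table <- function(ct_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# percent_input = 100 * 2^((ct_input - log2(1/input_fraction)) - ct_ip)  [formula v1]",
             con)
  utils::write.csv(as.data.frame(ct_table), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
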