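# tiny builders and independent oracles shared across tests

profile_of <- function(values, chrom = "chrT") {
  n <- length(values)
  timing_profile(data.frame(chrom = chrom,
                            start = seq(0, by = 1000, length.out = n),
                            end = seq(1000, by = 1000, length.out = n),
                            value = values, stringsAsFactors = FALSE))
}

track_of <- function(counts, profile, library_size = sum(counts)) {
  df <- as.data.frame(profile)
  df$value <- NULL
  df$count <- counts
  coverage_track(df, library_size = library_size)
}

fiber_of <- function(labels, starts, ends, length_kb = max(ends), id = "f1") {
  fiber_set(data.frame(fiber_id = id, length_kb = length_kb, label = labels,
                       start_kb = starts, end_kb = ends,
                       stringsAsFactors = FALSE))
}

# brute-force one-sided D: explicit loop over every bin
ks_d_oracle <- function(a, b) {
  d <- -Inf
  for (i in seq_len(a$n_bins)) d <- max(d, a$cdf[i] - b$cdf[i])
  max(d, 0)
}

# percentile by hand: sort and linearly interpolate at h = (n-1)p + 1
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# full enumeration of the Mann-Whitney null over all rank assignments
mw_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(N, na)
  us <- apply(combos, 2, function(ix) sum(seq_len(N)[ix]) - na * (na + 1) / 2)
  u_small <- min(u_obs, na * nb - u_obs)
  min(1, 2 * mean(us <= u_small))
}

# binned one-sided KS permutation oracle: both samples drawn from the pooled
# density as n pseudo-observations over the bins
ks_perm_oracle <- function(a, b, d_obs, n = 100, reps = 10000, chunk = 5000) {
  pooled <- (a$density + b$density) / 2
  hits <- 0
  done <- 0
  while (done < reps) {
    m <- min(chunk, reps - done)
    ca <- stats::rmultinom(m, n, pooled)
    cb <- stats::rmultinom(m, n, pooled)
    da <- apply(ca, 2, cumsum) / n
    db <- apply(cb, 2, cumsum) / n
    hits <- hits + sum(apply(da - db, 2, max) >= d_obs - 1e-12)
    done <- done + m
  }
  hits / reps
}
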