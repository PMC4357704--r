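#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The two-sided
#' p-value is exact — from the full null distribution of U, equivalent to
#' enumerating every arrangement — when there are no ties and
#' `n_a * n_b <= exact_limit`; otherwise it uses the normal approximation
#' with tie correction and continuity correction. Two identical samples of
#' constants give p = 1.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_limit Largest `n_a * n_b` for which the exact null
#'   distribution is used (tie-free data only).
#' @param alternative `"two.sided"` (default), or the one-sided
#'   `"greater"` / `"less"` (is `a` stochastically greater / less than `b`),
#'   for directional hypotheses stated a priori.
#' @return List `U` (for sample `a`), `U_b`, `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
mann_whitney <- function(a, b, exact_limit = 400,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("mann_whitney: both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  U_b <- na * nb - U_a
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = U_a, U_b = U_b, p_value = 1, method = "degenerate"))
  }
  if (!has_ties && na * nb <= exact_limit) {
    cnt <- u_null_distribution(na, nb)       # counts over U = 0..na*nb
    tail_leq <- function(u) sum(cnt[seq_len(u + 1)]) / choose(N, na)
    p <- switch(alternative,
                two.sided = 2 * tail_leq(min(U_a, U_b)),
                greater = tail_leq(U_b),     # large U_a = small U_b
                less = tail_leq(U_a))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(U = U_a, U_b = U_b, p_value = 1, method = "degenerate"))
    }
    z <- U_a - mu
    # continuity correction, applied toward the tested tail
    z <- switch(alternative,
                two.sided = z - sign(z) * 0.5,
                greater = z - 0.5,
                less = z + 0.5) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal"
  }
  list(U = U_a, U_b = U_b, p_value = min(p, 1), method = method)
}

# Null counts of arrangements with U = u, u = 0..n*m (no ties). U values
# over all choose(n+m, n) rank assignments follow the Gaussian binomial
# coefficient [n+m, n]_q = prod_i (1 - q^(m+i)) / (1 - q^i); the coefficient
# of q^u is the number of arrangements with statistic u (counts of partitions
# of u into at most n parts each <= m). Exact integer-valued polynomial
# arithmetic in doubles (counts stay far below 2^53 for n*m <= 400).
u_null_distribution <- function(n, m) {
  u_max <- n * m
  f <- numeric(u_max + 1)
  f[1] <- 1
  for (i in seq_len(n)) {
    g <- f
    k <- m + i
    if (k <= u_max) {
      g[(k + 1):(u_max + 1)] <- g[(k + 1):(u_max + 1)] - f[1:(u_max - k + 1)]
    }
    for (u in i:u_max) {            # divide by (1 - q^i): series division
      g[u + 1] <- g[u + 1] + g[u + 1 - i]
    }
    f <- g
  }
  f
}

#' Chi-square test on replication-figure class counts
#'
#' Compares two vectors of class counts (same classes) with the classic
#' two-sample chi-square: expected counts come from the pooled class
#' proportions, `X2 = sum (obs - exp)^2 / exp` over both samples, with
#' `df = classes - 1`. Classes whose pooled expected count is zero are
#' dropped with a warning and the degrees of freedom adjusted.
#'
#' @param counts_a,counts_b Named non-negative count vectors over the same
#'   classes (e.g. `figure_class_counts` from [classify_figures()]).
#' @return List `statistic`, `df`, `p_value`, `dropped` (class names).
#' @export
#' @examples
#' chi_square_counts(c(x = 50, y = 50), c(x = 25, y = 75))$statistic  # 13.33
chi_square_counts <- function(counts_a, counts_b) {
  counts_a <- unclass(counts_a); counts_b <- unclass(counts_b)
  if (is.null(names(counts_a)) || is.null(names(counts_b)) ||
      !setequal(names(counts_a), names(counts_b))) {
    stop("chi_square_counts: counts must be named over the same class set",
         call. = FALSE)
  }
  counts_b <- counts_b[names(counts_a)]
  pooled <- counts_a + counts_b
  dropped <- names(pooled)[pooled == 0]
  if (length(dropped)) {
    warning(sprintf("chi_square_counts: dropping empty classes: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    keep <- pooled > 0
    counts_a <- counts_a[keep]; counts_b <- counts_b[keep]
    pooled <- pooled[keep]
  }
  n_a <- sum(counts_a); n_b <- sum(counts_b)
  if (n_a == 0 || n_b == 0) {
    stop("chi_square_counts: each sample needs at least one observation",
         call. = FALSE)
  }
  prop <- pooled / (n_a + n_b)
  exp_a <- n_a * prop; exp_b <- n_b * prop
  x2 <- sum((counts_a - exp_a)^2 / exp_a) + sum((counts_b - exp_b)^2 / exp_b)
  df <- length(pooled) - 1L
  list(statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE),
       dropped = dropped)
}
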