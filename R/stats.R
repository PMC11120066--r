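#' @title Validation statistics
#' @description Measured-vs-predicted comparison utilities: signed percent
#'   differences with per-group summaries, and a from-scratch two-tailed
#'   Mann-Whitney U test (exact by enumeration / counting distribution for
#'   small samples, normal approximation with tie and continuity correction
#'   otherwise).
#' @name stats_validate
NULL

#' Signed percent difference
#'
#' `100 * (measured - calculated) / calculated`; positive when the
#' measurement exceeds the calculation.
#'
#' @param measured,calculated numeric vectors; `calculated` must be
#'   nonzero.
#' @return percent difference(s).
#' @export
percent_difference <- function(measured, calculated) {
  if (any(calculated == 0))
    .bs_stop("percent_difference: zero denominator")
  100 * (measured - calculated) / calculated
}

#' Summarize measured-vs-calculated differences by group
#'
#' Per group: mean of |percent difference|, sample SD (n-1) of the absolute
#' differences, and maximum; plus the global maximum.  Signed summaries are
#' included alongside.
#'
#' @param measured,calculated numeric vectors.
#' @param group grouping factor (e.g. distance class or direction).
#' @return a `comparison_report`: list with `by_group` (data.frame) and
#'   `max_abs_pct`.
#' @export
summarize_differences <- function(measured, calculated, group) {
  if (length(measured) != length(calculated) ||
      length(measured) != length(group))
    .bs_stop("summarize_differences: length mismatch")
  d <- percent_difference(measured, calculated)
  g <- factor(group)
  if (any(table(g) < 2L))
    .bs_stop("summarize_differences: need >= 2 pairs per group")
  by <- do.call(rbind, lapply(levels(g), function(lv) {
    di <- d[g == lv]
    data.frame(group = lv, n = length(di),
               mean_abs_pct = mean(abs(di)),
               sd_abs_pct = stats::sd(abs(di)),
               max_abs_pct = max(abs(di)),
               mean_signed_pct = mean(di),
               sd_signed_pct = stats::sd(di))
  }))
  structure(list(by_group = by, max_abs_pct = max(abs(d))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Measured vs calculated percent differences\n")
  print(x$by_group, row.names = FALSE)
  cat(sprintf("Global maximum |difference|: %.2f%%\n", x$max_abs_pct))
  invisible(x)
}

# exact null counting distribution of U (no ties): number of n1-subsets of
# ranks 1..N with each rank-sum; identical to full enumeration of
# C(N, n1) labelings.  Cached.
.u_null_distribution <- function(n1, n2) {
  key <- paste0("udist_", n1, "_", n2)
  if (!is.null(.bs_cache[[key]])) return(.bs_cache[[key]])
  N <- n1 + n2
  maxsum <- sum((N - n1 + 1):N)
  # dp[k+1, s+1] = number of k-subsets of {1..i} with sum s
  dp <- matrix(0, n1 + 1L, maxsum + 1L)
  dp[1L, 1L] <- 1
  for (i in seq_len(N)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      shifted <- c(rep(0, i), dp[k, seq_len(maxsum + 1L - i)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  counts <- dp[n1 + 1L, ]                  # indexed by rank-sum s (s = idx-1)
  minsum <- n1 * (n1 + 1) / 2
  u <- (minsum:maxsum) - minsum            # U = R1 - n1(n1+1)/2
  prob <- counts[minsum:maxsum + 1L] / choose(N, n1)
  out <- list(u = u, prob = prob, cdf = cumsum(prob))
  .bs_cache[[key]] <- out
  out
}

# all C(N, n1) label assignments (cached combination matrix)
.combn_cached <- function(N, n1) {
  key <- paste0("combn_", N, "_", n1)
  if (is.null(.bs_cache[[key]]))
    .bs_cache[[key]] <- utils::combn(N, n1)
  .bs_cache[[key]]
}

#' Two-tailed Mann-Whitney U test (from scratch)
#'
#' U is computed from midrank rank sums (`U = R1 - n1(n1+1)/2` for the
#' first sample).  The two-tailed p-value is `min(1, 2 min(P(U <= u),
#' P(U >= u)))` under the permutation null, which the implementation
#' evaluates three ways:
#' * `exact`, no ties: the tie-free counting distribution of U (dynamic
#'   programming; identical to enumerating all `C(n1+n2, n1)` labelings);
#' * `exact`, with ties: explicit enumeration of all labelings of the
#'   observed midranks (feasible up to `C(n1+n2, n1)` ~ 2e5);
#' * `normal`: large-sample normal approximation with midrank tie
#'   correction and a 0.5 continuity correction.
#'
#' Mode `"auto"` is exact for total n <= 12 and normal otherwise, so the
#' four-direction clinical comparison (n ~ 21 per arm) uses the
#' approximation while small problems stay exact.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return a `rank_test_result`: `U` (for `x`), `n1`, `n2`, `p_value`,
#'   `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) .bs_stop("mann_whitney_u: empty sample")
  N <- n1 + n2
  v <- c(x, y)
  r <- rank(v)                      # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(v) > 0L
  use_exact <- mode == "exact" || (mode == "auto" && N <= 12L)

  if (use_exact && !has_ties) {
    d <- .u_null_distribution(n1, n2)
    u0 <- round(U)
    ple <- d$cdf[match(u0, d$u)]
    pge <- 1 - if (u0 == d$u[1L]) 0 else d$cdf[match(u0, d$u) - 1L]
    p <- min(1, 2 * min(ple, pge))
    method <- "exact"
  } else if (use_exact && has_ties) {
    if (choose(N, n1) > 2e5)
      .bs_stop("mann_whitney_u: exact test with ties infeasible at this n; ",
               "use mode = \"normal\"")
    cmb <- .combn_cached(N, n1)
    us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= U + eps), mean(us >= U - eps)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(v)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      if (abs(U - mu) < 0.5) z <- 0
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  structure(list(U = U, n1 = n1, n2 = n2, p_value = p, method = method),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-tailed p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}
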