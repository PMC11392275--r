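# The two tests the dosage analysis relies on, implemented in-package:
# the Pearson chi-square contingency test and the Wilcoxon rank-sum test
# with an exact enumeration mode for small samples.

#' Pearson chi-square contingency test
#'
#' Statistic `sum((O - E)^2 / E)` with `E = rowsum x colsum / total`,
#' `df = (r - 1)(c - 1)`, p-value from the upper chi-square tail. With
#' `yates = TRUE` (2x2 tables only) `|O - E|` is reduced by 0.5 before
#' squaring. No correction is applied by default.
#'
#' @param table r x c matrix (or table) of non-negative integer counts;
#'   no row or column marginal may be zero.
#' @param yates apply the continuity correction (2x2 only).
#' @return list: `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_square_test <- function(table, yates = FALSE) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("negative counts")
  if (any(x != round(x))) stop("counts must be integral")
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least a 2x2 table")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column marginal")
  E <- outer(rs, cs) / sum(x)
  d <- abs(x - E)
  if (yates) {
    if (!all(dim(x) == c(2L, 2L)))
      stop("Yates correction applies to 2x2 tables only")
    d <- pmax(d - 0.5, 0)
  }
  stat <- sum(d^2 / E)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

# exact null distribution of the rank-sum of n observations drawn from
# the pooled midranks r (length n + m): all choose(n + m, n) subsets.
# The distribution depends only on the midrank multiset and n, so it is
# cached (untied samples of equal sizes share one distribution).
.ranksum_cache <- new.env(parent = emptyenv())

exact_ranksum_dist <- function(r, n) {
  key <- paste(c(n, sort(r)), collapse = ",")
  hit <- .ranksum_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- combn(length(r), n)
  dist <- colSums(matrix(r[idx], nrow = n))
  if (length(ls(.ranksum_cache)) < 32)
    .ranksum_cache[[key]] <- dist
  dist
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' The statistic is the rank sum of `x` in the pooled sample (midranks
#' for ties). `EXACT` mode enumerates the permutation distribution of
#' the rank sum (all arrangements of the pooled, possibly tied,
#' midranks) and returns `min(1, 2 * min(lower tail, upper tail))`, each
#' tail including the observed value; it is available when
#' `min(n, m) <= 10` and at most 1e6 arrangements exist. `NORMAL` mode
#' uses the tie-corrected normal approximation with continuity
#' correction. `AUTO` picks `EXACT` when feasible.
#'
#' @param x,y numeric samples, both non-empty.
#' @param mode `"AUTO"`, `"EXACT"` or `"NORMAL"`.
#' @return list: `statistic` (rank sum of `x`), `p.value`, `mode`
#'   (the mode actually used).
#' @export
wilcoxon_test <- function(x, y, mode = c("AUTO", "EXACT", "NORMAL")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  feasible <- min(n, m) <= 10 && choose(n + m, min(n, m)) <= 1e6
  if (mode == "AUTO") mode <- if (feasible) "EXACT" else "NORMAL"
  if (mode == "EXACT") {
    if (!feasible) stop("exact enumeration not feasible for these sizes")
    dist <- exact_ranksum_dist(r, n)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(dist <= W + eps), mean(dist >= W - eps)))
  } else {
    N <- n + m
    ties <- table(r)
    E <- n * (N + 1) / 2
    V <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (V <= 0) {
      p <- 1
    } else {
      z <- W - E
      z <- (z - sign(z) * 0.5) / sqrt(V)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(statistic = W, p.value = p, mode = mode)
}
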