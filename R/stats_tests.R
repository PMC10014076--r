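#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test for a location difference between two small groups of
#' per-replicate estimates. With `n_a + n_b <= 12` the null distribution of
#' the rank sum is enumerated exactly over all assignments of the pooled
#' (mid)ranks to group a; larger samples use the normal approximation with
#' tie and continuity corrections.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with `statistic` (rank sum W of group a), `p_value`,
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("domain error: empty group")
  if (anyNA(a) || anyNA(b)) stop("domain error: missing values")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))  # midranks for ties
  W <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  if (n <= 12L) {
    sums <- utils::combn(r, n_a, sum)
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p_value = 1,
                               method = "normal_approximation"))
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = W, p_value = p, method = "normal_approximation")
}

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance t test with `n_a + n_b - 2` degrees of freedom.
#' Degenerate zero-variance inputs are reported rather than raised: equal
#' means give `p = 1`, unequal means give the `p -> 0` limit with a
#' `degenerate` flag.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @return list with `statistic` (t), `df`, `p_value`, `degenerate`.
#' @export
students_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("domain error: need >= 2 per group")
  n_a <- length(a); n_b <- length(b)
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1) * stats::var(a) + (n_b - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(list(statistic = 0, df = df, p_value = 1, degenerate = TRUE))
    }
    return(list(statistic = sign(delta) * Inf, df = df, p_value = 0,
                degenerate = TRUE))
  }
  t <- delta / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}
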