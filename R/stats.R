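#' Two-sided Wilcoxon rank-sum test with common-language effect size
#'
#' Mann-Whitney U statistics are computed from the rank sums with midranks
#' for ties: `U1 = n1*n2 + n1*(n1+1)/2 - R1` (and symmetrically `U2`), so
#' `U1 + U2 = n1*n2`.  The two-sided p-value is exact (via the null U
#' distribution) when `min(n1, n2) <= 8` and there are no ties, otherwise a
#' normal approximation with tie correction and continuity correction is
#' used, matching the behaviour of standard rank-sum implementations at the
#' large sample sizes typical of per-cell metrics.  The common-language
#' effect size is `f = min(U1, U2) / (n1 * n2)`, the area under the ROC
#' curve of the two samples folded to `[0, 0.5]`; the directional variant
#' `auc = P(x > y) + P(x = y)/2` is also reported.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_limit use the exact null distribution when the smaller
#'   sample has at most this many observations and there are no ties.
#' @return An object of class `ranksum_result` with `U1`, `U2`, `R1`, `R2`,
#'   `p`, `cles`, `auc`, `n1`, `n2` and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' ranksum(c(1, 3), c(2, 4))$cles  # 0.25
#' @export
ranksum <- function(x, y, exact_limit = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("non-finite sample values", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  R2 <- sum(r) - R1
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  ntot <- n1 + n2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab)
  has_ties <- tie_term > 0
  if (min(n1, n2) <= exact_limit && !has_ties) {
    method <- "exact"
    ## U1 follows the Wilcoxon U null distribution (symmetric about n1*n2/2)
    mu <- n1 * n2 / 2
    p <- if (U1 <= mu) 2 * pwilcox(U1, n1, n2)
         else 2 * (1 - pwilcox(U1 - 1, n1, n2))
    p <- min(1, p)
  } else {
    method <- "normal_approx"
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((ntot + 1) - tie_term / (ntot * (ntot - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence of a shift
    } else {
      z <- (U1 - mu - 0.5 * sign(U1 - mu)) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(U1 = U1, U2 = U2, R1 = R1, R2 = R2, p = p,
                 cles = min(U1, U2) / (n1 * n2),
                 auc = U2 / (n1 * n2),
                 n1 = n1, n2 = n2, method = method),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf(paste0("<ranksum_result> n1 = %d, n2 = %d: U = (%.1f, %.1f), ",
                     "p = %.4g (%s), CLES f = %.4g\n"),
              x$n1, x$n2, x$U1, x$U2, x$p, x$method, x$cles))
  invisible(x)
}

#' Common-language effect size
#'
#' `f = min(U1, U2) / (n1 * n2)`: the probability that a randomly drawn
#' observation of one sample exceeds a randomly drawn observation of the
#' other, folded so that 0.5 means full overlap and 0 full separation (the
#' direction is intentionally dropped; see the `auc` field of [ranksum()]
#' for the signed variant).  Ties contribute 1/2 per pair.
#'
#' @inheritParams ranksum
#' @return The effect size `f` in `[0, 0.5]`.
#' @export
cles <- function(x, y) ranksum(x, y)$cles

#' Pearson correlation of two per-cell metrics
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, two-sided `p`, `n` and `method`.
#' @export
pearson_corr <- function(x, y) .corr_wrap(x, y, "pearson")

#' Spearman rank correlation of two per-cell metrics
#'
#' Pearson correlation of the midranks; used when a monotone rather than
#' linear association is expected.
#'
#' @inheritParams pearson_corr
#' @return list with `r`, two-sided `p`, `n` and `method`.
#' @export
spearman_corr <- function(x, y) .corr_wrap(x, y, "spearman")

.corr_wrap <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(x, y, method = method, alternative = "two.sided", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}
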