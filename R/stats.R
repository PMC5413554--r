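## Nonparametric tests used throughout the comparative analyses. The exact
## small-sample behaviour is part of the method contract: Mann-Whitney and
## Spearman p-values come from full enumeration at paper-scale group sizes,
## and the Fisher p is the two-sided hypergeometric tail sum.

#' Two-sided Mann-Whitney test
#'
#' U is computed by rank sums with midranks for ties. The two-sided p-value is
#' exact -- obtained by enumerating all `choose(nA+nB, nA)` assignments of the
#' pooled (mid)ranks -- whenever `nA + nB <= exact_limit`; beyond that a normal
#' approximation with tie correction and continuity correction is used. The
#' exact p is `P(|U - nA*nB/2| >= |U_obs - nA*nB/2|)` under the enumeration.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_limit switchover for the exact enumeration (default 20).
#' @return list with `U` (for group `a`), `p`, `method`, and `direction`
#'   (which group has the larger rank sum, or `"none"`).
#' @export
mann_whitney_two_sided <- function(a, b, exact_limit = 20) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_limit) {
    idx <- combn(n, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(Ua - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(Ua - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  direction <- if (Ua > mu) "first" else if (Ua < mu) "second" else "none"
  list(U = Ua, p = p, method = method, direction = direction)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' p is the sum of hypergeometric point probabilities of all tables with the
#' same margins whose probability does not exceed that of the observed table
#' (up to a `1 + 1e-7` tolerance factor). A table with any zero margin is
#' degenerate: p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  x <- tab[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(x, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Spearman rank correlation with exact small-sample p
#'
#' rho uses midranks. For `n <= exact_n` the two-sided p-value is computed by
#' full enumeration of rank arrangements (permutation null); for larger n the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used. Constant input
#' is flagged degenerate (rho undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_n switchover for the exact permutation p (default 10).
#' @return list with `rho`, `p`, `n`, `method`, `degenerate`.
#' @export
spearman_test <- function(x, y, exact_n = 10) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "degenerate", degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    p <- spearman_perm_p_cpp(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method, degenerate = FALSE)
}
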