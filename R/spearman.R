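# Spearman rank correlation with exact permutation p-values at small n.
# Ties get mean ranks; two-sided p throughout.

.perm_cache <- new.env(parent = emptyenv())

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
.allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- .allPermutations(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    row <- 0L
    for (pos in seq_len(n)) {
      block <- matrix(0L, nrow(sub), n)
      block[, pos] <- n
      block[, -pos] <- sub
      out[row + seq_len(nrow(sub)), ] <- block
      row <- row + nrow(sub)
    }
    out
  }
  if (n <= 9L) .perm_cache[[key]] <- perms
  perms
}

#' Spearman correlation with a two-sided p-value
#'
#' Ranks use the mean-rank convention for ties.  For `n <= 9` the p-value is
#' exact: the observed correlation is compared against the full permutation
#' distribution obtained by permuting one vector's ranks over all `n!`
#' orderings.  For larger `n` the usual t approximation
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom is used.
#' A constant vector has no defined rank correlation: the result is flagged
#' `defined = FALSE` with `r` and `p` set to `NA`.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `r`, `p`, `n`, `defined`, and `method`
#'   (`"exact_permutation"` or `"t_approximation"`).
#' @examples
#' spearmanTest(1:5, c(2, 4, 6, 8, 10))  # r = 1, exact p = 2/120
#' @export
spearmanTest <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE,
                method = "undefined_constant"))
  r <- stats::cor(x, y, method = "spearman")
  if (n <= 9L) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- .allPermutations(n)
    ryp <- matrix(ry[perms], nrow(perms), n)
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    mx <- mean(rx); my <- mean(ry)
    r_all <- (as.vector(ryp %*% rx) - n * mx * my) / ((n - 1) * sx * sy)
    p <- mean(abs(r_all) >= abs(r) - 1e-12)
    method <- "exact_permutation"
  } else {
    r2 <- min(r * r, 1)
    if (1 - r2 < .Machine$double.eps) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t_approximation"
  }
  list(r = r, p = p, n = n, defined = TRUE, method = method)
}

# strict threshold test with a numeric guard: a correlation computed to be
# within 1e-9 of the printed threshold counts as equal to it, so "r = 0.5"
# never passes "r > 0.5" through floating-point noise in the rank algebra
.strictlyAbove <- function(r, thresh) !is.na(r) & r > thresh + 1e-9

# point-estimate-only Spearman rho (used where only the r > threshold test
# matters, e.g. downstream-target evidence and immune-signature selection)
.spearmanRho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} m * p_(j) / j`, capped at 1,
#' reported in the input order.  Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  stopifnot(is.numeric(p))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}
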