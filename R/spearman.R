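# Spearman rank correlation on mid-ranks with the large-sample t approximation.

# internal: column-wise mid-ranks of a matrix
midrank_cols <- function(m) {
  apply(m, 2L, rank, ties.method = "average")
}

# internal: all pairwise Spearman rho between columns of X and Y plus
# t-approximation p-values. Returns list(rho, p) of ncol(X) x ncol(Y)
# matrices; columns with zero rank variance give NA (flagged, never 0).
spearman_matrix <- function(X, Y) {
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n >= 3L)
  RX <- scale(midrank_cols(X))   # centered, unit-variance ranks
  RY <- scale(midrank_cols(Y))
  rho <- crossprod(RX, RY) / (n - 1)
  rho[!is.finite(rho)] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(rho = rho, p = p, n = n)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties) and a two-sided p-value from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; pairs with missing
#'   values are dropped.
#' @return A one-row tibble with `rho`, `p_value`, `n`. A constant input
#'   leaves `rho` and `p_value` `NA` (undefined, flagged as non-correlated).
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40)) # rho = 1
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("spearman_rho needs n >= 3 complete pairs")
  res <- spearman_matrix(cbind(x), cbind(y))
  tibble(rho = as.numeric(res$rho), p_value = as.numeric(res$p),
         n = length(x))
}
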