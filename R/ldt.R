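#' Centered cross-product blocks for a pair of exon matrices
#'
#' Computes the blocks `A11`, `A22`, `A12` (and `A21 = t(A12)`) of the
#' centered cross-product matrix of the stacked sample vectors, i.e.
#' `A_ij = sum_k (x_k^(i) - xbar^(i)) (x_k^(j) - xbar^(j))'`, which equals
#' `(n - 1)` times the unbiased covariance estimator of the corresponding
#' block. Exact symmetry of the diagonal blocks is enforced.
#'
#' @param x p x n matrix (exons by samples) of the first variable set.
#' @param y q x n matrix of the second set, sharing the same ordered sample
#'   axis (column names, when present on both, must agree).
#' @return an object of class `ldt_cross_products` with elements `A11`,
#'   `A22`, `A12`, `A21`, `mean1`, `mean2`, `n`, `p`, `q`.
#' @export
ldt_cross_products <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) {
    stop("sample-axis mismatch: ", ncol(x), " vs ", ncol(y), " columns")
  }
  if (!is.null(colnames(x)) && !is.null(colnames(y)) &&
      !identical(colnames(x), colnames(y))) {
    stop("sample-axis mismatch: column names differ between the two blocks")
  }
  n <- ncol(x)
  if (n < 2L) stop("at least 2 samples are required")
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  xc <- x - m1
  yc <- y - m2
  A11 <- tcrossprod(xc)
  A22 <- tcrossprod(yc)
  A11 <- (A11 + t(A11)) / 2
  A22 <- (A22 + t(A22)) / 2
  A12 <- tcrossprod(xc, yc)
  structure(
    list(A11 = A11, A22 = A22, A12 = A12, A21 = t(A12),
         mean1 = m1, mean2 = m2, n = n, p = nrow(x), q = nrow(y)),
    class = "ldt_cross_products"
  )
}

#' Large-dimensional trace statistic
#'
#' Computes `L_n = tr(A21 A11^-1 A12 A22^-1)`, the sum of squared sample
#' canonical correlations between two variable sets. The inverses are never
#' formed explicitly; the trace is evaluated through linear solves, guarded
#' by a reciprocal-condition estimate.
#'
#' @param x either an [ldt_cross_products()] object, or a p x n matrix (in
#'   which case `y` must be the q x n companion block).
#' @param y optional q x n matrix; ignored when `x` is a cross-product
#'   object.
#' @return the trace statistic, a number in \[0, min(p, q)\].
#' @export
ldt_statistic <- function(x, y = NULL) {
  b <- if (inherits(x, "ldt_cross_products")) x else ldt_cross_products(x, y)
  if (rcond_sym(b$A11) < 1e-12 || rcond_sym(b$A22) < 1e-12) {
    stop("singular or ill-conditioned within-block cross-products; ",
         "remove zero-variance exons before testing")
  }
  P <- solve(b$A11, b$A12)       # A11^-1 A12, p x q
  Q <- solve(b$A22, b$A21)       # A22^-1 A21, q x p
  sum(P * t(Q))                  # tr(P Q)
}

# reciprocal condition estimate for a symmetric PSD matrix
rcond_sym <- function(a) {
  if (nrow(a) == 1L) {
    return(if (a[1L] > 0) 1 else 0)
  }
  rcond(a)
}

#' Asymptotic null moments of the trace statistic
#'
#' Under independence of the two blocks, the trace statistic has asymptotic
#' mean `E = q * p / (n - 1)` and variance
#' `V = 2 p q (n - 1 - p) (n - 1 - q) / (n - 1)^4`, valid when
#' `n - 1 > max(p, q)` (outside this regime `V` is non-positive and the
#' within-block cross-products are singular).
#'
#' @param p,q exon counts of the two blocks (>= 1).
#' @param n sample size; must satisfy `n - 1 > max(p, q)`.
#' @return list with elements `E` and `V` (`V > 0`).
#' @export
ldt_moments <- function(p, q, n) {
  if (p < 1L || q < 1L) stop("'p' and 'q' must be >= 1")
  if (n - 1 <= max(p, q)) {
    stop("unsupported regime: need n - 1 > max(p, q) (got p = ", p,
         ", q = ", q, ", n = ", n, "); filter exons to reduce dimensions")
  }
  list(
    E = q * p / (n - 1),
    V = 2 * p * q * (n - 1 - p) * (n - 1 - q) / (n - 1)^4
  )
}

#' Test independence of two exon-expression matrices
#'
#' One-sided large-dimensional trace test of the null hypothesis that the
#' between-block covariance is zero (no co-expression). The standardized
#' statistic `T = (L_n - E) / sqrt(V)` is referred to its asymptotic
#' standard-normal null; a co-expression edge is placed when `T` exceeds the
#' upper `alpha` quantile `Z_alpha`, equivalently when
#' `p-value = 1 - Phi(T) < alpha`. Exons with zero variance across samples
#' are removed first (with a warning) since they make the within-block
#' cross-products singular.
#'
#' @param x,y `isoform_matrix` objects or plain p x n / q x n matrices
#'   sharing the same ordered sample axis.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return an object of classes `ldt_test` and `htest` with components
#'   `statistic` (`T`), `estimate` (`L_n`), `parameter` (`p`, `q`, `n`),
#'   `p.value`, plus `E`, `V`, `alpha`, `critical.value` (`Z_alpha`) and the
#'   logical `edge` decision.
#' @examples
#' set.seed(1)
#' pair <- simulate_pair(p1 = 5, p2 = 5, n = 100, c0 = 0.6)
#' ldt_test(pair$x, pair$y)
#' @export
ldt_test <- function(x, y, alpha = 0.05) {
  stopifnot_scalar_prob(alpha, "alpha")
  nm_x <- if (inherits(x, "isoform_matrix")) x$isoform_id else
    deparse(substitute(x))
  nm_y <- if (inherits(y, "isoform_matrix")) y$isoform_id else
    deparse(substitute(y))
  if (inherits(x, "isoform_matrix")) x <- x$values
  if (inherits(y, "isoform_matrix")) y <- y$values
  x <- drop_zero_variance(as.matrix(x), nm_x)
  y <- drop_zero_variance(as.matrix(y), nm_y)
  if (nrow(x) == 0L || nrow(y) == 0L) {
    stop("no exon with non-zero variance left to test")
  }
  b <- ldt_cross_products(x, y)
  mom <- ldt_moments(b$p, b$q, b$n)
  L <- ldt_statistic(b)
  T_stat <- (L - mom$E) / sqrt(mom$V)
  z_alpha <- qnorm(1 - alpha)
  res <- list(
    statistic = c(T = T_stat),
    parameter = c(p = b$p, q = b$q, n = b$n),
    p.value = pnorm(T_stat, lower.tail = FALSE),
    estimate = c(L_n = L),
    E = mom$E, V = mom$V,
    alpha = alpha, critical.value = z_alpha,
    edge = T_stat > z_alpha,
    alternative = "the between-block covariance is non-zero (one-sided)",
    method = "Large-dimensional trace test of independence",
    data.name = paste(nm_x, "and", nm_y)
  )
  class(res) <- c("ldt_test", "htest")
  res
}

drop_zero_variance <- function(m, label) {
  v <- rowSums((m - rowMeans(m))^2)
  bad <- v == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance exon(s) removed from ", label)
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' @export
print.ldt_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n")
  cat("data: ", x$data.name, "\n")
  cat(sprintf("L_n = %.5f, E = %.5f, V = %.6f, T = %.4f, p-value = %.5g\n",
              x$estimate[["L_n"]], x$E, x$V, x$statistic[["T"]], x$p.value))
  cat(sprintf("dimensions: p = %d, q = %d, n = %d\n",
              x$parameter[["p"]], x$parameter[["q"]], x$parameter[["n"]]))
  cat(sprintf("edge at alpha = %g (Z = %.4f): %s\n\n", x$alpha,
              x$critical.value, if (x$edge) "yes" else "no"))
  invisible(x)
}

# lean statistic for tight simulation loops: pre-validated numeric blocks
ldt_stat_fast <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  A12 <- tcrossprod(xc, yc)
  sum(solve(tcrossprod(xc), A12) * t(solve(tcrossprod(yc), t(A12))))
}
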