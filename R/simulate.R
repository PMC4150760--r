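#' Simulate one pair of exon-expression matrices
#'
#' Draws a pair of multivariate-normal exon blocks for the power study.
#' Independent pairs are i.i.d. standard normal, `Z_i ~ N(0, I)`. Dependent
#' (co-expressed) pairs follow `X_i = Z_i + c0 * Z_m^(p_i)`, where the
#' shared component `Z_m^(p_i)` is the first `p_i` coordinates of `Z_1` when
#' `p1 >= p2` and of `Z_2` otherwise, and the constant `c0 >= 0` sets the
#' dependence strength (an inverse noise level). Note the literal
#' consequence that the larger block becomes `(1 + c0) Z_1` when
#' `p1 >= p2`. With `c0 = 0` the dependent draw coincides with the
#' independent one.
#'
#' Randomness comes from the current RNG state; call [set.seed()] for
#' reproducibility.
#'
#' @param p1,p2 exon counts (>= 1) of the two blocks.
#' @param n sample size.
#' @param c0 dependence constant (>= 0); default 0.6.
#' @param dependent draw a co-expressed pair (default `TRUE`)?
#' @return list with matrices `x` (p1 x n) and `y` (p2 x n).
#' @export
simulate_pair <- function(p1, p2, n, c0 = 0.6, dependent = TRUE) {
  if (p1 < 1L || p2 < 1L) stop("'p1' and 'p2' must be >= 1")
  if (n < 2L) stop("'n' must be >= 2")
  if (c0 < 0) stop("'c0' must be >= 0")
  z1 <- matrix(rnorm(p1 * n), p1, n)
  z2 <- matrix(rnorm(p2 * n), p2, n)
  if (!dependent || c0 == 0) {
    return(list(x = z1, y = z2))
  }
  zm <- if (p1 >= p2) z1 else z2
  list(
    x = z1 + c0 * zm[seq_len(p1), , drop = FALSE],
    y = z2 + c0 * zm[seq_len(p2), , drop = FALSE]
  )
}

#' Monte-Carlo power study of the trace test
#'
#' For each replication, draws one dependent pair (strength `c0`) and
#' `mix_ratio` independent pairs, applies the one-sided trace test at level
#' `alpha`, and pools the decisions into confusion counts: TP (dependent,
#' rejected), FN (dependent, accepted), FP (independent, rejected), TN
#' (independent, accepted). Precision, recall (power), false-positive rate
#' and F-score are computed from the pooled counts.
#'
#' The 10:1 independent:dependent default mix is a documented reconstruction
#' of the composition behind the published F-score design, which does not
#' state it; it is exposed as a parameter so its effect can be studied.
#'
#' @param p1,p2 exon counts of the two blocks.
#' @param n sample size; must satisfy `n - 1 > max(p1, p2)`.
#' @param c0 dependence constant for the dependent arm.
#' @param alpha significance level (default 0.05).
#' @param reps number of replications (default 1000).
#' @param mix_ratio independent pairs drawn per dependent pair (default 10).
#' @param seed optional integer seed (local to this call).
#' @return an object of class `ldt_sim`: list with `counts` (named vector
#'   `TP`, `FP`, `TN`, `FN`), `precision`, `recall`, `fpr`, `f_score` and
#'   the configuration.
#' @examples
#' ldt_power_sim(p1 = 5, p2 = 5, n = 100, c0 = 0.6, reps = 200, seed = 1)
#' @export
ldt_power_sim <- function(p1 = 5, p2 = 5, n = 100, c0 = 0.6, alpha = 0.05,
                          reps = 1000, mix_ratio = 10, seed = NULL) {
  stopifnot_scalar_prob(alpha, "alpha")
  if (reps < 1L) stop("'reps' must be >= 1")
  if (mix_ratio < 1L) stop("'mix_ratio' must be >= 1")
  if (n - 1 <= max(p1, p2)) {
    stop("unsupported regime: need n - 1 > max(p1, p2)")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  mom <- ldt_moments(p1, p2, n)
  zc <- qnorm(1 - alpha)
  sdv <- sqrt(mom$V)
  tp <- fp <- 0L
  for (r in seq_len(reps)) {
    d <- simulate_pair(p1, p2, n, c0, dependent = TRUE)
    if ((ldt_stat_fast(d$x, d$y) - mom$E) / sdv > zc) tp <- tp + 1L
    for (j in seq_len(mix_ratio)) {
      d0 <- simulate_pair(p1, p2, n, dependent = FALSE)
      if ((ldt_stat_fast(d0$x, d0$y) - mom$E) / sdv > zc) fp <- fp + 1L
    }
  }
  counts <- c(TP = tp, FP = fp, TN = reps * mix_ratio - fp, FN = reps - tp)
  structure(
    list(
      counts = counts,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = tp / reps,
      fpr = fp / (reps * mix_ratio),
      f_score = f_score(counts),
      p1 = p1, p2 = p2, n = n, c0 = c0, alpha = alpha,
      reps = reps, mix_ratio = mix_ratio, seed = seed
    ),
    class = "ldt_sim"
  )
}

#' F-score from confusion counts
#'
#' `F = 2 p r / (p + r)` with precision `p = TP / (TP + FP)` and recall
#' `r = TP / (TP + FN)`. When either denominator is zero the score is
#' defined as 0, with a warning.
#'
#' @param counts named numeric vector with elements `TP`, `FP`, `FN` (extra
#'   elements such as `TN` are ignored), or an `ldt_sim` object.
#' @return the F-score, in \[0, 1\].
#' @export
f_score <- function(counts) {
  if (inherits(counts, "ldt_sim")) counts <- counts$counts
  tp <- counts[["TP"]]
  fp <- counts[["FP"]]
  fn <- counts[["FN"]]
  if (tp + fp == 0 || tp + fn == 0) {
    warning("undefined precision or recall (no positive calls or no ",
            "positive truths); F-score defined as 0")
    return(0)
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @export
print.ldt_sim <- function(x, ...) {
  cat(sprintf(
    "Trace-test power study: p1 = %d, p2 = %d, n = %d, c0 = %g\n",
    x$p1, x$p2, x$n, x$c0))
  cat(sprintf("  alpha = %g, reps = %d, independent:dependent mix = %d:1\n",
              x$alpha, x$reps, x$mix_ratio))
  cat(sprintf("  TP = %d, FP = %d, TN = %d, FN = %d\n",
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["TN"]],
              x$counts[["FN"]]))
  cat(sprintf(
    "  precision = %.3f, recall (power) = %.3f, FPR = %.4f, F = %.3f\n",
    x$precision, x$recall, x$fpr, x$f_score))
  invisible(x)
}

#' @export
as.data.frame.ldt_sim <- function(x, ...) {
  data.frame(
    c0 = x$c0, p1 = x$p1, p2 = x$p2, n = x$n, reps = x$reps,
    mix_ratio = x$mix_ratio, alpha = x$alpha,
    seed = x$seed %||% NA_integer_,
    TP = x$counts[["TP"]], FP = x$counts[["FP"]],
    TN = x$counts[["TN"]], FN = x$counts[["FN"]],
    precision = x$precision, recall = x$recall, fpr = x$fpr,
    f_score = x$f_score
  )
}

#' Run the simulation grid of the power study
#'
#' Evaluates [ldt_power_sim()] over a grid of dependence constants, exon-
#' count pairs and sample sizes (defaults: `c0` in 0.2/0.4/0.6, dimensions
#' 5-5, 20-20 and 20-5, `n` in 25/50/75/100). Cells violating
#' `n - 1 > max(p1, p2)` are reported as unsupported (`NA` scores) rather
#' than dropped; on the default grid the trace test supports every cell,
#' including those where the total exon count exceeds the sample size.
#' Per-cell seeds are derived deterministically from `seed`.
#'
#' @param c0 numeric vector of dependence constants.
#' @param dims list of 2-vectors `c(p1, p2)`.
#' @param n numeric vector of sample sizes.
#' @param reps replications per cell (the published design uses 100,000;
#'   desk-scale runs use fewer).
#' @param mix_ratio independent pairs per dependent pair (default 10).
#' @param alpha significance level.
#' @param seed base integer seed.
#' @return an object of classes `ldt_sim_table` and `data.frame`, one row
#'   per cell with counts, precision, recall and F-score; printing renders
#'   the F-scores as a `c0` x dimensions by sample-size table.
#' @export
table1_grid <- function(c0 = c(0.2, 0.4, 0.6),
                        dims = list(c(5, 5), c(20, 20), c(20, 5)),
                        n = c(25, 50, 75, 100),
                        reps = 1000, mix_ratio = 10, alpha = 0.05,
                        seed = NULL) {
  cells <- expand.grid(ci = seq_along(c0), di = seq_along(dims),
                       ni = seq_along(n))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cc <- c0[cells$ci[i]]
    dd <- dims[[cells$di[i]]]
    nn <- n[cells$ni[i]]
    cell_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    if (nn - 1 <= max(dd)) {
      out[[i]] <- data.frame(
        c0 = cc, p1 = dd[1L], p2 = dd[2L], n = nn, reps = reps,
        mix_ratio = mix_ratio, alpha = alpha,
        seed = cell_seed %||% NA_integer_,
        TP = NA_integer_, FP = NA_integer_, TN = NA_integer_,
        FN = NA_integer_, precision = NA_real_, recall = NA_real_,
        fpr = NA_real_, f_score = NA_real_,
        note = "unsupported: n - 1 <= max(p1, p2)"
      )
    } else {
      sim <- ldt_power_sim(dd[1L], dd[2L], nn, cc, alpha, reps, mix_ratio,
                           seed = cell_seed)
      out[[i]] <- cbind(as.data.frame(sim), note = "")
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$c0, out$p1, out$p2, out$n), ]
  rownames(out) <- NULL
  class(out) <- c("ldt_sim_table", "data.frame")
  out
}

#' @export
print.ldt_sim_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  ns <- sort(unique(df$n))
  cat("F-scores of the trace test on simulated data\n")
  cat(sprintf("  (reps = %s, mix = %d:1, alpha = %g)\n",
              paste(unique(df$reps), collapse = "/"),
              df$mix_ratio[1L], df$alpha[1L]))
  header <- sprintf("%-5s %-9s %s", "c0", "dims",
                    paste(sprintf("n=%-7d", ns), collapse = ""))
  cat(header, "\n")
  combos <- unique(df[, c("c0", "p1", "p2")])
  for (i in seq_len(nrow(combos))) {
    sel <- df$c0 == combos$c0[i] & df$p1 == combos$p1[i] &
      df$p2 == combos$p2[i]
    vals <- vapply(ns, function(nn) {
      v <- df$f_score[sel & df$n == nn]
      if (length(v) == 0L || is.na(v)) "NA" else formatC(v, digits = digits,
                                                         format = "f")
    }, character(1))
    cat(sprintf("%-5g %-9s %s\n", combos$c0[i],
                paste0(combos$p1[i], "-", combos$p2[i]),
                paste(sprintf("%-9s", vals), collapse = "")))
  }
  invisible(x)
}
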