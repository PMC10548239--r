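## Exact conditional inference on 2x2 carrier/condition tables.
##
## The table convention throughout the package is
##     a = carriers with condition      b = non-carriers with condition
##     c = carriers without condition   d = non-carriers without condition
## Conditioning on both margins, the carrier count among the with-condition
## group follows a (noncentral) hypergeometric distribution; all inference
## here is conditional on the margins.

.as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  # `c` is a cell name here, so base::c must be called explicitly
  if (is.null(b)) {
    x <- if (is.matrix(a)) as.vector(t(a)) else as.vector(a)
    if (length(x) != 4L) stop("a 2x2 table needs exactly four counts")
    a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  }
  x <- base::c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("2x2 cells must be non-negative integers")
  setNames(as.integer(round(x)), names(x))
}

# support of the conditional distribution of cell `a`
.support_2x2 <- function(t) {
  n1 <- t[["a"]] + t[["b"]]   # with-condition margin
  n2 <- t[["c"]] + t[["d"]]   # without-condition margin
  k  <- t[["a"]] + t[["c"]]   # carrier margin
  seq.int(max(0L, k - n2), min(k, n1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test of association in a carrier-by-condition table.
#' The two-sided p-value uses the point-probability criterion: it is the
#' sum of hypergeometric point probabilities of all tables with the
#' observed margins that are no more probable than the observed table
#' (comparison made with relative tolerance `1 + 1e-7`, the convention of
#' mainstream statistical environments). A table with a zero row or column
#' margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Cell counts: carriers with condition, non-carriers with
#'   condition, carriers without condition, non-carriers without condition.
#'   Alternatively `a` may be a length-4 vector or 2x2 matrix (row-major).
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(10, 6, 5, 31)
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .as_2x2(a, b, c, d)
  n1 <- t[["a"]] + t[["b"]]; n2 <- t[["c"]] + t[["d"]]; k <- t[["a"]] + t[["c"]]
  if (n1 == 0L || n2 == 0L || k == 0L || (t[["b"]] + t[["d"]]) == 0L)
    return(1)
  supp <- .support_2x2(t)
  probs <- dhyper(supp, n1, n2, k)
  p_obs <- dhyper(t[["a"]], n1, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

# log unnormalised conditional likelihood weights over the support
.cond_weights <- function(supp, n1, n2, k) {
  lchoose(n1, supp) + lchoose(n2, k - supp)
}

# conditional distribution of `a` at log-odds-ratio theta
.cond_dist <- function(supp, lw, theta) {
  lp <- lw + supp * theta
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Conditional maximum-likelihood odds ratio with exact confidence interval
#'
#' Estimates the odds ratio of a 2x2 table by maximising the noncentral
#' hypergeometric likelihood conditional on both margins (the root of the
#' conditional score equation E\[A; or\] = a), and inverts one-sided exact
#' tests at 2.5% each side for a 95% confidence interval. When the observed
#' table sits on the boundary of the conditional support the estimate is 0
#' or `Inf` and the corresponding interval is one-sided.
#'
#' @inheritParams fisher_exact_two_sided
#' @param conf_level Confidence level for the exact interval.
#' @return A list with `or` (the conditional MLE), `ci` (length-2 numeric)
#'   and `degenerate` (TRUE when a margin is zero and the odds ratio is
#'   undefined, in which case `or` is `NA`).
#' @examples
#' cmle_odds_ratio(10, 6, 5, 31)$or  # 9.73
#' @export
cmle_odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  t <- .as_2x2(a, b, c, d)
  n1 <- t[["a"]] + t[["b"]]; n2 <- t[["c"]] + t[["d"]]; k <- t[["a"]] + t[["c"]]
  supp <- .support_2x2(t)
  if (n1 == 0L || n2 == 0L || k == 0L || (t[["b"]] + t[["d"]]) == 0L ||
      length(supp) == 1L)
    return(list(or = NA_real_, ci = base::c(NA_real_, NA_real_),
                degenerate = TRUE))

  lw <- .cond_weights(supp, n1, n2, k)
  obs <- t[["a"]]
  alpha <- (1 - conf_level) / 2

  cond_mean <- function(theta) sum(supp * .cond_dist(supp, lw, theta))
  solve_theta <- function(f, lo = -40, hi = 40) {
    # f is monotone increasing in theta for all equations used here
    uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
  }

  or <- if (obs == max(supp)) Inf else if (obs == min(supp)) 0 else
    exp(solve_theta(function(th) cond_mean(th) - obs))

  # exact tail inversion: lower limit from P(A >= a), upper from P(A <= a)
  p_upper_tail <- function(theta) sum(.cond_dist(supp, lw, theta)[supp >= obs])
  p_lower_tail <- function(theta) sum(.cond_dist(supp, lw, theta)[supp <= obs])

  ci_lo <- if (obs == min(supp)) 0 else
    exp(solve_theta(function(th) p_upper_tail(th) - alpha))
  ci_hi <- if (obs == max(supp)) Inf else
    exp(solve_theta(function(th) alpha - p_lower_tail(th)))

  list(or = or, ci = base::c(ci_lo, ci_hi), degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for `m` tests. Kept as an explicit helper because the
#' number of tests in a burden scan is the number of genes (or variants)
#' with qualifying data, which the caller must supply.
#'
#' @param p Raw p-value(s) in (0, 1].
#' @param m Positive integer number of tests.
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, m == round(m), all(p > 0), all(p <= 1))
  pmin(1, m * p)
}
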