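#' 2x2 carrier table
#'
#' The contingency table underlying every burden comparison in the package:
#' `a` case carriers, `b` case non-carriers, `c` control carriers, `d`
#' control non-carriers, so that `a + b` is the number of cases and `c + d`
#' the number of controls.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return An object of class `"two_by_two"`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("two_by_two validation error: cells must be non-negative integers",
         call. = FALSE)
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two> cases %d/%d carriers, controls %d/%d carriers\n",
              x$a, x$a + x$b, x$c, x$c + x$d))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' Computes the Pearson statistic `sum((O - E)^2 / E)` with expectations
#' from the row/column margins and the upper-tail p-value from the
#' chi-square distribution with 1 degree of freedom. No Yates correction is
#' applied: the published per-gene burden p-values this package reproduces
#' are uncorrected Pearson values. Degenerate tables with an empty carrier
#' or non-carrier column return `(statistic = 0, p = 1)`; an empty row
#' (a group of size zero) is an error.
#'
#' @param table a [two_by_two()].
#' @return list with `statistic` and `p`.
#' @export
#' @examples
#' pearson_chi2(two_by_two(3, 34, 1, 533))$p  # ~2.3e-08
pearson_chi2 <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  # double precision: the margin product overflows 32-bit integers already
  # at a few hundred individuals per group
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  cc <- as.numeric(table$c); d <- as.numeric(table$d)
  r1 <- a + b; r2 <- cc + d
  if (r1 == 0 || r2 == 0) {
    stop("degenerate 2x2 table: a group has zero individuals", call. = FALSE)
  }
  c1 <- a + cc; c2 <- b + d
  if (c1 == 0 || c2 == 0) {
    return(list(statistic = 0, p = 1))
  }
  n <- r1 + r2
  # algebraically identical to the four-cell (O-E)^2/E sum for a 2x2 table
  stat <- n * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Log point-probabilities of the (central) hypergeometric pmf over the full
# support, conditioning on margins: n_case cases, n_control controls,
# k total carriers. Returned as a list(support, logp). Log-factorials via
# lgamma keep the computation exact to well past 10 significant digits for
# cohort-scale tables.
hyper_logpmf <- function(n_case, n_control, k) {
  n <- n_case + n_control
  support <- max(0L, k - n_control):min(k, n_case)
  lchoose_ <- function(m, x) {
    lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1)
  }
  logp <- lchoose_(n_case, support) + lchoose_(n_control, k - support) -
    lchoose_(n, k)
  list(support = support, logp = logp)
}

# Numerically stable sum of exp(logp) over a subset.
sum_exp <- function(logp) {
  if (!length(logp)) return(0)
  m <- max(logp)
  exp(m) * sum(exp(logp - m))
}

# One- and two-sided Fisher p-values for every value of `a` in the support
# of the margin set (n_case, n_control, k). Shared by fisher_exact() and the
# exhaustive oracle-equivalence tests so that the sweep exercises the exact
# code path the scalar interface uses.
fisher_pvalues_support <- function(n_case, n_control, k) {
  h <- hyper_logpmf(n_case, n_control, k)
  s <- length(h$support)
  p_one <- vapply(seq_len(s), function(i) sum_exp(h$logp[i:s]), double(1L))
  # two-sided: sum all tables at most as probable as the observed one,
  # with the customary (1 + 1e-7) relative fuzz on the equality comparison
  p_two <- vapply(seq_len(s), function(i) {
    keep <- h$logp <= h$logp[i] + log1p(1e-07)
    sum_exp(h$logp[keep])
  }, double(1L))
  list(support = h$support, p_one_sided = pmin(p_one, 1),
       p_two_sided = pmin(p_two, 1))
}

#' Fisher's exact test on a 2x2 carrier table
#'
#' Exact conditional inference under the hypergeometric model, computed by
#' direct log-factorial accumulation over the table support (no asymptotics,
#' no library shortcut). `"one_sided_enrichment"` is the probability of `a`
#' or more case carriers given all margins — the alternative of interest in
#' a case enrichment scan; `"two_sided"` sums the probabilities of all
#' tables whose point probability does not exceed the observed one (with a
#' `1 + 1e-7` relative tolerance on ties, matching the conventional
#' definition).
#'
#' @param table a [two_by_two()].
#' @param alternative `"one_sided_enrichment"` or `"two_sided"`.
#' @return The p-value. Tables whose carrier column margin is 0 (or equal to
#'   the cohort size) have a single admissible table, so the p-value is 1.
#' @export
#' @examples
#' fisher_exact(two_by_two(3, 34, 1, 533), "one_sided_enrichment")
fisher_exact <- function(table,
                         alternative = c("one_sided_enrichment",
                                         "two_sided")) {
  stopifnot(inherits(table, "two_by_two"))
  alternative <- match.arg(alternative)
  n_case <- table$a + table$b
  n_control <- table$c + table$d
  if (n_case == 0 || n_control == 0) {
    stop("degenerate 2x2 table: a group has zero individuals", call. = FALSE)
  }
  k <- table$a + table$c
  pv <- fisher_pvalues_support(n_case, n_control, k)
  i <- match(table$a, pv$support)
  if (alternative == "one_sided_enrichment") pv$p_one_sided[i]
  else pv$p_two_sided[i]
}

#' One-tailed pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimate and
#' `df = n1 + n2 - 2`, testing the one-tailed alternative that the case
#' mean exceeds the control mean (the direction of a mutational-burden
#' excess). Degenerate zero-variance inputs follow fixed conventions: equal
#' means give p = 0.5; unequal means give p = 0 or 1 according to the
#' direction of the difference.
#'
#' @param case_values,control_values numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p_one_tailed`, `mean_case`, `mean_control`.
#' @export
mean_burden_t_test <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 individuals for the t-test",
         call. = FALSE)
  }
  m1 <- mean(case_values); m2 <- mean(control_values)
  df <- n1 + n2 - 2
  sp2 <- (sum((case_values - m1)^2) + sum((control_values - m2)^2)) / df
  if (sp2 == 0) {
    p <- if (m1 == m2) 0.5 else if (m1 > m2) 0 else 1
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- stats::pt(t, df = df, lower.tail = FALSE)
  }
  list(t = t, df = df, p_one_tailed = p, mean_case = m1, mean_control = m2)
}
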