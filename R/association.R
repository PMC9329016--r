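#' Pairwise-complete 2x2 table for a disease pair
#'
#' Cross-tabulates presence/absence of two diseases among the subjects in
#' whom both were measured (pairwise deletion: a subject missing either
#' disease contributes nothing to this pair, but still counts for other
#' pairs).
#'
#' @param cohort A [cohort_table()].
#' @param i,j Disease names (or column indices), `i != j`.
#' @return An object of class `two_by_two` with counts `n11`, `n10`, `n01`,
#'   `n00` (`n11` = both present; first index refers to disease `i`).
#' @export
pair_counts <- function(cohort, i, j) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.numeric(i)) i <- cohort$disease_names[i]
  if (is.numeric(j)) j <- cohort$disease_names[j]
  if (identical(i, j)) stop("pair_counts requires two distinct diseases")
  if (!all(c(i, j) %in% cohort$disease_names))
    stop("unknown disease name(s): ",
         paste(setdiff(c(i, j), cohort$disease_names), collapse = ", "))
  xi <- cohort$diseases[, i]
  xj <- cohort$diseases[, j]
  ok <- !is.na(xi) & !is.na(xj)
  xi <- xi[ok]; xj <- xj[ok]
  two_by_two(n11 = sum(xi & xj), n10 = sum(xi & !xj),
             n01 = sum(!xi & xj), n00 = sum(!xi & !xj),
             diseases = c(i, j))
}

#' @rdname pair_counts
#' @param n11,n10,n01,n00 Non-negative cell counts.
#' @param diseases Optional length-2 label vector.
#' @export
two_by_two <- function(n11, n10, n01, n00, diseases = NULL) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("table must contain at least one subject")
  structure(as.list(cells), diseases = diseases, class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  d <- attr(x, "diseases") %||% c("i", "j")
  matrix(c(x$n11, x$n01, x$n10, x$n00), 2, 2,
         dimnames = list(paste0(d[1], c("=1", "=0")),
                         paste0(d[2], c("=1", "=0"))))
}

#' Phi coefficient of a 2x2 table
#'
#' The phi coefficient is the Pearson correlation specialised to two binary
#' variables: \eqn{\phi = (n_{11}n_{00} - n_{10}n_{01}) / \sqrt{r_1 r_0 c_1
#' c_0}} with row/column margins \eqn{r, c}. It ranges from −1 (perfect
#' inverse relationship) through 0 (no relationship) to +1 (perfect direct
#' relationship). When any margin is zero phi is undefined and `NA` is
#' returned — never a silent 0.
#'
#' @param t A `two_by_two` (or anything coercible via its counts).
#' @return Numeric in \[−1, 1\], or `NA_real_` for a degenerate table.
#' @export
#' @examples
#' phi_coefficient(two_by_two(30, 10, 20, 40)) # 1000/sqrt(6e6)
phi_coefficient <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  phi_from_counts(t$n11, t$n10, t$n01, t$n00)
}

#' Relative risk of disease co-occurrence
#'
#' The co-occurrence relative risk \eqn{RR_{ij} = (C_{ij} N) / (P_i P_j)},
#' where \eqn{C_{ij}} is the number of patients with both diseases, \eqn{N}
#' the total number of patients in the pairwise-complete table and
#' \eqn{P_i, P_j} the numbers of patients with each disease — the observed
#' joint count relative to its expectation under independence. The 95% CI
#' uses a delta-method normal approximation on the log scale, propagating
#' multinomial cell variation through \eqn{\log RR = \log n_{11} + \log N -
#' \log P_i - \log P_j} (a non-negative sum-of-squares variance).
#'
#' @param t A `two_by_two`.
#' @param conf.level Confidence level (default 0.95).
#' @return Named numeric `c(rr, lower, upper)`; `rr = NA` when either margin
#'   is zero, `rr = 0` with `NA` bounds when there is no co-occurrence.
#' @export
relative_risk <- function(t, conf.level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  C <- t$n11
  N <- t$n11 + t$n10 + t$n01 + t$n00
  Pi <- t$n11 + t$n10
  Pj <- t$n11 + t$n01
  if (Pi == 0 || Pj == 0)
    return(c(rr = NA_real_, lower = NA_real_, upper = NA_real_))
  rr <- C * N / (Pi * Pj)
  if (C == 0) return(c(rr = 0, lower = NA_real_, upper = NA_real_))
  # delta method on log RR, cells treated as independent Poisson:
  # gradients wrt (n11, n10, n01, n00)
  g <- c(1 / C + 1 / N - 1 / Pi - 1 / Pj,
         1 / N - 1 / Pi, 1 / N - 1 / Pj, 1 / N)
  se <- sqrt(sum(c(t$n11, t$n10, t$n01, t$n00) * g^2))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  c(rr = rr, lower = rr * exp(-z * se), upper = rr * exp(z * se))
}

#' Association test for a 2x2 table
#'
#' Pearson chi-square test (no continuity correction, so the identity
#' \eqn{X^2 = N\phi^2} holds exactly) when every expected cell count is at
#' least 5; otherwise Fisher's exact test, two-sided — the conventional
#' reading of "requirements for the chi-square test not met".
#'
#' @param t A `two_by_two`.
#' @return List with `p_value`, `test_used` (`"chi-square"` or `"fisher"`)
#'   and `statistic` (`NA` for Fisher).
#' @export
pair_test <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- matrix(c(t$n11, t$n01, t$n10, t$n00), 2, 2)
  N <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / N
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(p_value = unname(ct$p.value), test_used = "chi-square",
         statistic = unname(ct$statistic))
  } else {
    list(p_value = stats::fisher.test(m)$p.value, test_used = "fisher",
         statistic = NA_real_)
  }
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval for a proportion from beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n-x+1)` (0 when x = 0), upper =
#' `qbeta(1-alpha/2, x+1, n-x)` (1 when x = n).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param conf.level Confidence level (default 0.95).
#' @return Named numeric `c(estimate, lower, upper)`.
#' @export
#' @examples
#' prevalence_ci(235, 1726) # point estimate 13.6%
prevalence_ci <- function(x, n, conf.level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf.level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(estimate = x / n, lower = lower, upper = upper)
}

#' Filter diseases by prevalence across strata
#'
#' A disease is retained iff its prevalence (over non-missing entries) is at
#' least `threshold` in at least one of the supplied strata; the comparison
#' is inclusive and the input ordering is preserved. With the default 3.5%
#' threshold and all four phenotype subgroups supplied jointly, every
#' stratum network shares one node set.
#'
#' @param strata A list of [cohort_table()]s sharing `disease_names` (a
#'   single cohort is accepted).
#' @param threshold Minimum prevalence (default 0.035).
#' @return Character vector of retained disease names.
#' @export
filter_diseases <- function(strata, threshold = 0.035) {
  if (inherits(strata, "cohort_table")) strata <- list(strata)
  stopifnot(length(strata) >= 1L, threshold >= 0)
  nm <- strata[[1L]]$disease_names
  for (s in strata)
    if (!identical(s$disease_names, nm))
      stop("all strata must share the same disease columns")
  keep <- Reduce(`|`, lapply(strata, function(s) {
    if (nrow(s$diseases) == 0L) return(rep(FALSE, length(nm)))
    prev <- validate_cohort(s, verbose = FALSE)$prevalence
    !is.na(prev) & prev >= threshold
  }))
  nm[keep]
}

#' All pairwise association statistics for one sample
#'
#' Long-format table over every unordered disease pair: pairwise-complete
#' counts, phi, co-occurrence RR with CI, and the chi-square/Fisher p-value.
#'
#' @param cohort A [cohort_table()].
#' @param diseases Diseases to include (default all).
#' @param conf.level Confidence level for the RR interval.
#' @return A `data.frame` with one row per pair, suitable for
#'   `write.csv()`.
#' @export
pair_stats <- function(cohort, diseases = cohort$disease_names,
                       conf.level = 0.95) {
  stopifnot(length(diseases) >= 2L)
  pr <- upper_pairs(length(diseases))
  rows <- lapply(seq_len(nrow(pr)), function(r) {
    i <- diseases[pr[r, 1L]]; j <- diseases[pr[r, 2L]]
    t <- pair_counts(cohort, i, j)
    rr <- relative_risk(t, conf.level)
    tst <- pair_test(t)
    data.frame(disease_i = i, disease_j = j,
               n11 = t$n11, n10 = t$n10, n01 = t$n01, n00 = t$n00,
               phi = phi_coefficient(t),
               rr = unname(rr["rr"]), rr_lower = unname(rr["lower"]),
               rr_upper = unname(rr["upper"]),
               p_value = tst$p_value, test_used = tst$test_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
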