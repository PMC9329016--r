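`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and a label
#'
#' Each stratum run consumes its own random stream, derived deterministically
#' from the base seed and a text label, so adding or reordering strata never
#' perturbs another stratum's draws.
#'
#' @param seed Integer base seed.
#' @param label Character label (e.g. a stratum name).
#' @return An integer in \[0, 2^31).
#' @export
derive_seed <- function(seed, label = "") {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Two-sided Fisher exact p for a 2x2 table via the hypergeometric mass,
# summing all outcomes no more probable than the observed one (the same
# convention as stats::fisher.test, including its 1e-7 relative tolerance).
# Used in the bootstrap hot loop where calling fisher.test per draw is too slow.
fisher_p_2x2 <- function(n11, n10, n01, n00) {
  m <- n11 + n10
  n <- n01 + n00
  k <- n11 + n01
  lo <- max(0L, k - n)
  hi <- min(k, m)
  d <- stats::dhyper(lo:hi, m, n, k)
  sum(d[d <= d[n11 - lo + 1L] * (1 + 1e-7)])
}

# phi over vectors of 2x2 cell counts; NA where any table margin is zero
# (phi is undefined there, and 0-filling would bias downstream means).
phi_from_counts <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10
  r0 <- n01 + n00
  c1 <- n11 + n01
  c0 <- n10 + n00
  den <- sqrt(r1) * sqrt(r0) * sqrt(c1) * sqrt(c0)
  phi <- (n11 * n00 - n10 * n01) / den
  phi[r1 == 0 | r0 == 0 | c1 == 0 | c0 == 0] <- NA_real_
  phi
}

# Percentile convention used throughout: linear interpolation between order
# statistics (quantile type 7), computed over defined draws only.
boot_quantile <- function(x, probs) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

upper_pairs <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
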