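#' Bootstrap configuration
#'
#' Controls the within-stratum resampling scheme: `n_resamples` bootstrap
#' draws (default 10 000, honouring "at least 10 000 re-samples"), each of
#' `resample_size` subjects drawn with replacement (default: the stratum
#' size; the stratified pipeline uses 800 for CB strata and 400 for Ex
#' strata, values close to the smallest group of each pair), and the
#' percentile used by the edge rule (default 0.025).
#'
#' @param n_resamples Number of bootstrap resamples (>= 1).
#' @param resample_size Subjects per resample (>= 2), or `NULL` for the
#'   stratum size.
#' @param percentile Lower tail probability for edge significance, in
#'   (0, 0.5).
#' @param seed Integer base seed; each stratum run derives its own stream
#'   from `(seed, label)` via [derive_seed()].
#' @param keep_p Compute per-resample chi-square/Fisher p-values (summarised
#'   as `mean_p`). Disable for large replication studies where only phi is
#'   needed.
#' @param keep_draws Retain the per-resample phi draw matrix (needed by
#'   [connectivity_overlap()]).
#' @return An object of class `boot_config`.
#' @export
boot_config <- function(n_resamples = 10000L, resample_size = NULL,
                        percentile = 0.025, seed = 1L,
                        keep_p = TRUE, keep_draws = TRUE) {
  stopifnot(n_resamples >= 1, percentile > 0, percentile < 0.5)
  if (!is.null(resample_size) && resample_size < 2)
    stop("resample_size must be at least 2")
  structure(list(n_resamples = as.integer(n_resamples),
                 resample_size = if (is.null(resample_size)) NULL
                                 else as.integer(resample_size),
                 percentile = percentile, seed = as.integer(seed),
                 keep_p = isTRUE(keep_p), keep_draws = isTRUE(keep_draws)),
            class = "boot_config")
}

#' Bootstrap pairwise association distributions within one stratum
#'
#' The resampling engine behind the stratified comorbidity networks. Each
#' resample draws `resample_size` subjects uniformly with replacement from
#' the stratum; for every unordered disease pair the pairwise-complete 2x2
#' table, phi, co-occurrence RR and (optionally) the chi-square/Fisher
#' p-value are computed, along with every disease's prevalence. Resamples in
#' which a pair's table has a zero margin contribute no phi draw for that
#' pair (phi is undefined there; zero-filling would bias the mean towards
#' zero) — the number of defined draws is reported as `n_defined`.
#'
#' Summaries per pair: `mean_phi`, the percentile bounds `phi_p025`/
#' `phi_p975` (linear interpolation between order statistics), `mean_rr`
#' and `mean_p`, each over defined draws.
#'
#' @param cohort A [cohort_table()] (a stratum).
#' @param diseases Diseases to analyse (default: all columns).
#' @param config A [boot_config()].
#' @param label Stratum label used for seed derivation and reporting
#'   (default: the cohort's `"stratum"` attribute, else `"cohort"`).
#' @return An object of class `bootstrap_result`: list with `pairs` (a
#'   data.frame of per-pair summaries), `draws` (resamples x pairs phi
#'   matrix, or `NULL`), `prevalence` (mean per-disease prevalence across
#'   resamples), `n_subjects`, `label`, `diseases` and the `config` echo.
#' @export
bootstrap_pairs <- function(cohort, diseases = NULL, config = boot_config(),
                            label = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "boot_config"))
  diseases <- diseases %||% cohort$disease_names
  if (!all(diseases %in% cohort$disease_names))
    stop("unknown disease(s): ",
         paste(setdiff(diseases, cohort$disease_names), collapse = ", "))
  label <- label %||% attr(cohort, "stratum") %||% "cohort"
  n <- nrow(cohort$diseases)
  if (n < 2L) stop("stratum must contain at least 2 subjects")
  m <- config$resample_size %||% n
  B <- config$n_resamples
  K <- length(diseases)
  if (K < 2L) stop("need at least 2 diseases")
  pr <- upper_pairs(K)
  P <- nrow(pr)
  lin <- (pr[, 2L] - 1L) * K + pr[, 1L]      # upper-triangle linear index
  lin_t <- (pr[, 1L] - 1L) * K + pr[, 2L]    # its transpose

  X <- cohort$diseases[, diseases, drop = FALSE]
  has_missing <- anyNA(X)
  X0 <- X; X0[is.na(X0)] <- 0L
  storage.mode(X0) <- "double"
  if (has_missing) { M <- 1 - is.na(X); storage.mode(M) <- "double" }

  draws <- matrix(NA_real_, B, P)
  rr_sum <- rr_n <- p_sum <- p_n <- numeric(P)
  prev_sum <- numeric(K)
  set.seed(derive_seed(config$seed, label))
  for (b in seq_len(B)) {
    idx <- sample.int(n, m, replace = TRUE)
    Xb <- X0[idx, , drop = FALSE]
    S11 <- crossprod(Xb)
    if (has_missing) {
      Mb <- M[idx, , drop = FALSE]
      Np <- crossprod(Mb)
      PiM <- crossprod(Xb, Mb)
      Npair <- Np[lin]
      pi_ <- PiM[lin]
      pj <- PiM[lin_t]
      prev_sum <- prev_sum + colSums(Xb) / colSums(Mb)
    } else {
      cs <- colSums(Xb)
      Npair <- rep.int(m, P)
      pi_ <- cs[pr[, 1L]]
      pj <- cs[pr[, 2L]]
      prev_sum <- prev_sum + cs / m
    }
    n11 <- S11[lin]
    n10 <- pi_ - n11
    n01 <- pj - n11
    n00 <- Npair - pi_ - pj + n11
    phi <- phi_from_counts(n11, n10, n01, n00)
    draws[b, ] <- phi
    ok <- pi_ > 0 & pj > 0 & Npair > 0
    rr_sum[ok] <- rr_sum[ok] +
      n11[ok] * Npair[ok] / (pi_[ok] * pj[ok])
    rr_n[ok] <- rr_n[ok] + 1
    if (config$keep_p) {
      defined <- !is.na(phi)
      pv <- rep(NA_real_, P)
      exp_min <- pmin(pi_ * pj, pi_ * (Npair - pj), (Npair - pi_) * pj,
                      (Npair - pi_) * (Npair - pj)) / Npair^2 * Npair
      chisq_ok <- defined & !is.na(exp_min) & exp_min >= 5
      pv[chisq_ok] <- stats::pchisq(Npair[chisq_ok] * phi[chisq_ok]^2, 1,
                                    lower.tail = FALSE)
      for (w in which(defined & !chisq_ok))
        pv[w] <- fisher_p_2x2(n11[w], n10[w], n01[w], n00[w])
      p_sum[defined] <- p_sum[defined] + pv[defined]
      p_n[defined] <- p_n[defined] + 1
    }
  }
  n_defined <- colSums(!is.na(draws))
  if (any(n_defined == 0L))
    warning(sprintf("%d pair(s) had no defined phi draw in any resample",
                    sum(n_defined == 0L)))
  q <- apply(draws, 2L, boot_quantile,
             probs = c(config$percentile, 1 - config$percentile))
  pairs <- data.frame(
    disease_i = diseases[pr[, 1L]],
    disease_j = diseases[pr[, 2L]],
    mean_phi = colMeans(draws, na.rm = TRUE),
    phi_p025 = q[1L, ],
    phi_p975 = q[2L, ],
    n_defined = n_defined,
    mean_rr = ifelse(rr_n > 0, rr_sum / rr_n, NA_real_),
    mean_p = ifelse(p_n > 0, p_sum / p_n, NA_real_),
    stringsAsFactors = FALSE)
  pairs$mean_phi[n_defined == 0L] <- NA_real_
  structure(list(pairs = pairs,
                 draws = if (config$keep_draws) draws else NULL,
                 prevalence = stats::setNames(prev_sum / B, diseases),
                 n_subjects = n, label = label, diseases = diseases,
                 config = config),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap result '%s': %d subjects, %d diseases, %d pairs, B = %d (m = %s)\n",
              x$label, x$n_subjects, length(x$diseases), nrow(x$pairs),
              x$config$n_resamples,
              x$config$resample_size %||% x$n_subjects))
  cat(sprintf("  network density (mean phi over all pairs): %.4f\n",
              network_density(x)))
  cat(sprintf("  significant edges (p%.1f percentile of phi > 0): %d\n",
              100 * x$config$percentile, nrow(significant_edges(x))))
  invisible(x)
}

#' Edges passing the bootstrap percentile rule
#'
#' A disease pair is a significant edge when the lower percentile (default
#' the 2.5th) of its bootstrap phi distribution is strictly greater than
#' zero.
#'
#' @param result A [bootstrap_pairs()] result.
#' @return `data.frame` of significant pairs (subset of `result$pairs`).
#' @export
significant_edges <- function(result) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (all(is.na(result$pairs$mean_phi)))
    stop("no pair has a defined phi distribution")
  keep <- !is.na(result$pairs$phi_p025) & result$pairs$phi_p025 > 0
  result$pairs[keep, , drop = FALSE]
}

#' Network density: mean phi over all candidate pairs
#'
#' Total network density is the unweighted mean of the per-pair bootstrap
#' mean phi over ALL retained pairs, significant or not (range −1 to 1).
#' Pairs whose phi was never defined are excluded with a message.
#'
#' @param result A [bootstrap_pairs()] result.
#' @return Numeric density.
#' @export
network_density <- function(result) {
  stopifnot(inherits(result, "bootstrap_result"))
  mp <- result$pairs$mean_phi
  if (all(is.na(mp))) stop("density undefined: no pair has a defined mean phi")
  if (anyNA(mp))
    message(sprintf("network_density: %d pair(s) with undefined mean phi excluded",
                    sum(is.na(mp))))
  mean(mp, na.rm = TRUE)
}

#' Node connectivity: aggregate phi of a disease with the rest of the network
#'
#' For each disease, the mean (default; scale-free in the number of nodes)
#' or sum of the bootstrap mean phi over its K − 1 incident pairs; incident
#' pairs with undefined mean phi are excluded.
#'
#' @param result A [bootstrap_pairs()] result.
#' @param mode `"mean"` or `"sum"`.
#' @return Named numeric vector, one value per disease.
#' @export
node_connectivity <- function(result, mode = c("mean", "sum")) {
  stopifnot(inherits(result, "bootstrap_result"))
  mode <- match.arg(mode)
  agg <- if (mode == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) sum(v, na.rm = TRUE)
  vapply(stats::setNames(result$diseases, result$diseases), function(d) {
    inc <- result$pairs$disease_i == d | result$pairs$disease_j == d
    v <- result$pairs$mean_phi[inc]
    if (all(is.na(v))) NA_real_ else agg(v)
  }, numeric(1L))
}

#' Compare one node's bootstrap connectivity between two strata
#'
#' For each stratum, the node's per-resample connectivity (mean phi over its
#' defined incident pairs within that resample) yields a bootstrap
#' distribution; the report gives each group's 2.5-97.5 percentile interval
#' and whether the intervals overlap. Overlapping intervals are read as "no
#' significant between-group difference" for that node. The report is
#' symmetric in the two results.
#'
#' @param result_a,result_b [bootstrap_pairs()] results run with
#'   `keep_draws = TRUE`.
#' @param node Disease name present in both results.
#' @param probs Interval probabilities (default `c(0.025, 0.975)`).
#' @return An object of class `connectivity_overlap`: list with `node`,
#'   `labels`, `interval_a`, `interval_b`, `overlap` (logical).
#' @export
connectivity_overlap <- function(result_a, result_b, node,
                                 probs = c(0.025, 0.975)) {
  stopifnot(inherits(result_a, "bootstrap_result"),
            inherits(result_b, "bootstrap_result"))
  one <- function(res) {
    if (!node %in% res$diseases)
      stop(sprintf("node '%s' absent from stratum '%s'", node, res$label))
    if (is.null(res$draws))
      stop("connectivity_overlap requires draws (run with keep_draws = TRUE)")
    inc <- res$pairs$disease_i == node | res$pairs$disease_j == node
    conn <- rowMeans(res$draws[, inc, drop = FALSE], na.rm = TRUE)
    boot_quantile(conn, probs)
  }
  ia <- one(result_a)
  ib <- one(result_b)
  structure(list(node = node, labels = c(result_a$label, result_b$label),
                 interval_a = ia, interval_b = ib,
                 overlap = ia[1L] <= ib[2L] && ib[1L] <= ia[2L]),
            class = "connectivity_overlap")
}

#' @export
print.connectivity_overlap <- function(x, ...) {
  cat(sprintf("Connectivity of '%s': %s [%.4f, %.4f] vs %s [%.4f, %.4f] -> %s\n",
              x$node, x$labels[1L], x$interval_a[1L], x$interval_a[2L],
              x$labels[2L], x$interval_b[1L], x$interval_b[2L],
              if (x$overlap) "intervals overlap (no significant difference)"
              else "intervals do not overlap"))
  invisible(x)
}
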