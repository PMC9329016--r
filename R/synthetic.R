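#' Attainable phi range for two binary margins
#'
#' With fixed marginal prevalences the joint probability of co-occurrence is
#' constrained by the Frechet-Hoeffding bounds \eqn{\max(0, p_i+p_j-1) \le
#' C \le \min(p_i, p_j)}; mapping these through the phi formula gives the
#' attainable phi interval. Planted associations outside this interval are
#' impossible for any joint distribution.
#'
#' @param p_i,p_j Marginal prevalences, strictly inside (0, 1).
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' phi_feasible_bounds(0.5, 0.5) # c(-1, 1)
phi_feasible_bounds <- function(p_i, p_j) {
  p_i <- unname(p_i); p_j <- unname(p_j)
  stopifnot(p_i > 0, p_i < 1, p_j > 0, p_j < 1)
  s <- sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  c(lower = (max(0, p_i + p_j - 1) - p_i * p_j) / s,
    upper = (min(p_i, p_j) - p_i * p_j) / s)
}

#' Upper-orthant probability of a standard bivariate normal
#'
#' \eqn{P(X > h, Y > k)} for standard normal margins with correlation `rho`,
#' computed by reducing the double integral to a single quadrature
#' \eqn{\int_h^\infty \varphi(x)\,\Phi((\rho x - k)/\sqrt{1-\rho^2})\,dx}.
#' Accurate to well below 1e-10; the comonotone/antithetic limits are
#' handled in closed form.
#'
#' @param h,k Thresholds.
#' @param rho Correlation in \[−1, 1\].
#' @return Probability in \[0, 1\].
#' @export
bvn_upper_prob <- function(h, k, rho) {
  stopifnot(abs(rho) <= 1)
  if (rho >= 1 - 1e-12)
    return(stats::pnorm(max(h, k), lower.tail = FALSE))
  if (rho <= -1 + 1e-12)
    return(max(0, stats::pnorm(-k) - stats::pnorm(h)))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((rho * x - k) / s)
  stats::integrate(f, h, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 400L)$value
}

#' Latent correlation achieving a target phi for two binary margins
#'
#' Solves for the bivariate-normal correlation `rho` such that thresholding
#' standard normal variates at the (1 − p) quantiles yields binary variables
#' whose phi coefficient equals `target_phi` (equivalently, whose joint
#' success probability equals \eqn{C = p_i p_j + \phi\sqrt{p_i(1-p_i)
#' p_j(1-p_j)}}). Root-finding drives the orthant probability to within
#' 1e-8 of `C`.
#'
#' @param p_i,p_j Marginal prevalences in (0, 1).
#' @param target_phi Desired phi, inside [phi_feasible_bounds()].
#' @return Latent correlation in (−1, 1).
#' @export
#' @examples
#' solve_latent_correlation(0.5, 0.5, 1 / 3) # 0.5 (closed-form check)
solve_latent_correlation <- function(p_i, p_j, target_phi) {
  b <- phi_feasible_bounds(p_i, p_j)
  if (target_phi < b["lower"] || target_phi > b["upper"])
    stop(sprintf("target phi %.4f infeasible for margins (%.3f, %.3f); feasible interval [%.4f, %.4f]",
                 target_phi, p_i, p_j, b["lower"], b["upper"]))
  if (abs(target_phi) < 1e-14) return(0)
  s <- sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  Ct <- p_i * p_j + target_phi * s
  h <- stats::qnorm(1 - p_i)
  k <- stats::qnorm(1 - p_j)
  f <- function(r) bvn_upper_prob(h, k, r) - Ct
  eps <- 1e-10
  if (f(1 - eps) <= 0) return(1 - eps)
  if (f(-1 + eps) >= 0) return(-1 + eps)
  root <- stats::uniroot(f, c(-1 + eps, 1 - eps), tol = 1e-12)$root
  if (abs(f(root)) > 1e-8)
    stop("latent-correlation solve did not reach tolerance 1e-8")
  root
}

project_psd <- function(R, max_perturb = 0.05) {
  e <- eigen(R, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin >= -1e-12) return(R)
  if (-lmin > max_perturb)
    stop(sprintf("pairwise phi targets are jointly unattainable: latent matrix eigenvalue %.4f below zero exceeds the projection tolerance %.2f",
                 lmin, max_perturb))
  warning(sprintf("latent correlation matrix not PSD (min eigenvalue %.2e); projected by eigenvalue clipping", lmin))
  v <- pmax(e$values, 1e-10)
  R2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(R2)
}

#' Specify a synthetic binary comorbidity cohort
#'
#' Defines the generative model for [generate_cohort()]: a latent
#' multivariate Gaussian thresholded at margin-matching quantiles
#' (Emrich-Piedmonte style), giving exact control over each disease's
#' prevalence and direct targeting of each pair's phi. Phenotype flags
#' (CB, Ex) are drawn independently of each other; when `stratum_mean_phi`
#' is supplied the four CB x Ex cells each receive their own constant
#' off-diagonal phi matrix (see Details) so that the pooled CB and Ex strata
#' attain planted network densities.
#'
#' @details With per-stratum mean-phi targets `stratum_mean_phi =
#'   list(cb = c(neg, pos), ex = c(neg, pos))`, cell phi values are the
#'   additive decomposition `m + alpha_cb + beta_ex` that reproduces both
#'   between-group gaps exactly; because all four cells share the same
#'   marginal prevalences, each pooled stratum's phi is the
#'   membership-weighted mean of its cells' phi.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param prevalences Named vector of marginal prevalences strictly in
#'   (0, 1); names become the disease names.
#' @param target_phi Symmetric phi matrix with unit diagonal (default:
#'   identity, i.e. independent diseases). Ignored when `stratum_mean_phi`
#'   or `cell_phi` is given.
#' @param cb_fraction,ex_fraction Phenotype-positive fractions in \[0, 1\].
#' @param stratum_mean_phi Optional `list(cb = c(neg, pos), ex = c(neg,
#'   pos))` of per-stratum mean pairwise phi targets.
#' @param cell_phi Optional named list of four phi matrices (or scalars),
#'   names `"CB-Ex-"`, `"CB-Ex+"`, `"CB+Ex-"`, `"CB+Ex+"`, overriding
#'   everything else.
#' @param missing_rate Per-disease probability that a cell is unmeasured,
#'   in \[0, 1); scalar or named vector.
#' @param seed Integer seed; the seed fully determines the generated
#'   cohort, including the missingness mask.
#' @return An object of class `cohort_spec`.
#' @seealso [copd_cohort_spec()] for a ready-made COPD-cohort-scale spec.
#' @export
cohort_spec <- function(n_subjects, prevalences, target_phi = NULL,
                        cb_fraction = 0.5, ex_fraction = 0.25,
                        stratum_mean_phi = NULL, cell_phi = NULL,
                        missing_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 2, length(prevalences) >= 2,
            all(prevalences > 0), all(prevalences < 1),
            cb_fraction >= 0, cb_fraction <= 1,
            ex_fraction >= 0, ex_fraction <= 1)
  if (is.null(names(prevalences)))
    names(prevalences) <- sprintf("D%02d", seq_along(prevalences))
  K <- length(prevalences)
  if (is.null(target_phi)) target_phi <- diag(K)
  check_phi_matrix <- function(M, what) {
    if (length(M) == 1L) M <- matrix(M, K, K) + (1 - M) * diag(K)
    if (!isSymmetric(unname(M)) || any(abs(diag(M) - 1) > 1e-12))
      stop(what, " must be symmetric with unit diagonal")
    for (a in seq_len(K - 1L)) for (b in seq((a + 1L), K)) {
      bd <- phi_feasible_bounds(prevalences[a], prevalences[b])
      if (M[a, b] < bd["lower"] || M[a, b] > bd["upper"])
        stop(sprintf("%s[%d,%d] = %.4f outside feasible phi interval [%.4f, %.4f] for margins (%.3f, %.3f)",
                     what, a, b, M[a, b], bd["lower"], bd["upper"],
                     prevalences[a], prevalences[b]))
    }
    M
  }
  if (!is.null(cell_phi)) {
    need <- c("CB-Ex-", "CB-Ex+", "CB+Ex-", "CB+Ex+")
    stopifnot(setequal(names(cell_phi), need))
    cell_phi <- lapply(stats::setNames(need, need), function(cl)
      check_phi_matrix(cell_phi[[cl]], paste0("cell_phi[['", cl, "']]")))
  } else if (!is.null(stratum_mean_phi)) {
    stopifnot(is.list(stratum_mean_phi),
              all(c("cb", "ex") %in% names(stratum_mean_phi)))
    cv <- cell_phi_from_stratum_means(stratum_mean_phi, cb_fraction, ex_fraction)
    cell_phi <- lapply(cv, function(v)
      check_phi_matrix(v, "derived cell phi"))
  } else {
    target_phi <- check_phi_matrix(target_phi, "target_phi")
  }
  missing_rate <- rep_len(missing_rate, K)
  stopifnot(all(missing_rate >= 0), all(missing_rate < 1))
  names(missing_rate) <- names(prevalences)
  structure(list(n_subjects = as.integer(n_subjects),
                 disease_names = names(prevalences),
                 prevalences = prevalences,
                 target_phi = target_phi,
                 cb_fraction = cb_fraction, ex_fraction = ex_fraction,
                 stratum_mean_phi = stratum_mean_phi,
                 cell_phi = cell_phi,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Additive 4-cell decomposition of per-stratum mean-phi targets.
# Both between-group gaps are preserved exactly; the two traits' implied
# overall means need not agree (and do not for the published targets), so
# the overall level splits the difference.
cell_phi_from_stratum_means <- function(sm, f_cb, f_ex) {
  cb <- unname(sm$cb); ex <- unname(sm$ex)  # c(neg, pos)
  gap_cb <- cb[1] - cb[2]
  gap_ex <- ex[1] - ex[2]
  m <- ((1 - f_cb) * cb[1] + f_cb * cb[2] +
        (1 - f_ex) * ex[1] + f_ex * ex[2]) / 2
  alpha <- c(`-` = f_cb * gap_cb, `+` = -(1 - f_cb) * gap_cb)
  beta  <- c(`-` = f_ex * gap_ex, `+` = -(1 - f_ex) * gap_ex)
  out <- list()
  for (a in c("-", "+")) for (b in c("-", "+"))
    out[[paste0("CB", a, "Ex", b)]] <- m + alpha[[a]] + beta[[b]]
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d subjects, %d diseases (seed %d)\n",
              x$n_subjects, length(x$disease_names), x$seed))
  cat(sprintf("  CB+ fraction %.3f, Ex+ fraction %.3f\n",
              x$cb_fraction, x$ex_fraction))
  if (!is.null(x$cell_phi))
    cat("  per-cell planted phi:",
        paste(sprintf("%s=%.4f", names(x$cell_phi),
                      vapply(x$cell_phi, function(m) m[1, 2], 0)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Precompute the latent-Gaussian structure of a spec
#'
#' Solves every pairwise latent correlation (one [solve_latent_correlation()]
#' call per disease pair per CB x Ex cell) and Cholesky-factorises the
#' resulting matrices, projecting to the nearest PSD correlation matrix when
#' pairwise targets are not jointly attainable (error beyond an eigenvalue
#' perturbation of 0.05). Pass the result to [generate_cohort()] to amortise
#' the solves over many replicate cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return Opaque list used by [generate_cohort()].
#' @export
latent_structure <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$prevalences
  K <- length(p)
  solve_matrix <- function(phi) {
    R <- diag(K)
    cache <- new.env(parent = emptyenv())
    for (a in seq_len(K - 1L)) for (b in seq((a + 1L), K)) {
      key <- sprintf("%.12g|%.12g|%.12g", p[a], p[b], phi[a, b])
      r <- cache[[key]] %||% solve_latent_correlation(p[a], p[b], phi[a, b])
      cache[[key]] <- r
      R[a, b] <- R[b, a] <- r
    }
    R <- project_psd(R)
    chol(R + diag(1e-9, K))
  }
  mats <- if (!is.null(spec$cell_phi)) {
    lapply(spec$cell_phi, solve_matrix)
  } else {
    list(all = solve_matrix(spec$target_phi))
  }
  list(chol = mats, thresholds = stats::qnorm(1 - p))
}

#' Generate a synthetic comorbidity cohort
#'
#' Draws a [cohort_table()] from a [cohort_spec()]: latent multivariate
#' normal variates per CB x Ex cell (or a single block when no per-stratum
#' structure is planted), thresholded at the (1 − p) quantiles; phenotype
#' flags Bernoulli(`cb_fraction`)/Bernoulli(`ex_fraction`), independent of
#' each other; missingness applied independently per cell at the per-disease
#' rate. Fully reproducible from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed (default `spec$seed`).
#' @param latent Optional precomputed [latent_structure()].
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(spec, seed = spec$seed, latent = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  latent <- latent %||% latent_structure(spec)
  n <- spec$n_subjects
  K <- length(spec$disease_names)
  set.seed(derive_seed(seed, "generate_cohort"))
  cb <- stats::rbinom(n, 1L, spec$cb_fraction)
  ex <- stats::rbinom(n, 1L, spec$ex_fraction)
  X <- matrix(NA_integer_, n, K, dimnames = list(NULL, spec$disease_names))
  if (length(latent$chol) == 1L) {
    groups <- list(all = seq_len(n))
  } else {
    cell <- paste0("CB", ifelse(cb == 1L, "+", "-"),
                   "Ex", ifelse(ex == 1L, "+", "-"))
    groups <- split(seq_len(n), factor(cell, levels = names(latent$chol)))
  }
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (!length(rows)) next
    Z <- matrix(stats::rnorm(length(rows) * K), length(rows), K) %*%
      latent$chol[[g]]
    X[rows, ] <- (Z > rep(latent$thresholds, each = length(rows))) * 1L
  }
  if (any(spec$missing_rate > 0)) {
    U <- matrix(stats::runif(n * K), n, K)
    X[U < rep(spec$missing_rate, each = n)] <- NA_integer_
  }
  cohort_table(X, cb = cb, ex = ex)
}

#' Simulate replicate cohorts from a spec
#'
#' @param object A [cohort_spec()].
#' @param nsim Number of replicate cohorts.
#' @param seed Base seed (default `object$seed`); replicate r uses
#'   `seed + r - 1`.
#' @param ... Unused.
#' @return A list of [cohort_table()]s (a single table when `nsim = 1`).
#' @export
simulate.cohort_spec <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% object$seed
  latent <- latent_structure(object)
  out <- lapply(seq_len(nsim), function(r)
    generate_cohort(object, seed = seed + r - 1L, latent = latent))
  if (nsim == 1) out[[1L]] else out
}

#' Spec emulating a published-scale COPD multimorbidity cohort
#'
#' A ready-made [cohort_spec()] at the scale of a multicentre COPD cohort:
#' 1726 subjects; 16 candidate comorbidities at realistic prevalences
#' (arterial hypertension 51%, obesity 35.9%, dyslipidaemia 57%, atrial
#' fibrillation 13.6%, underweight 2.4%, ...); chronic-bronchitis-positive
#' fraction 52% and severe-exacerbator fraction 24.2%; per-disease
#' missingness reflecting variables not collected at every centre (e.g.
#' dyslipidaemia unavailable for one whole centre); and per-stratum planted
#' mean pairwise phi of 0.098 (CB−) vs 0.050 (CB+) and 0.082 (Ex−) vs
#' 0.072 (Ex+). Two diseases (underweight, osteoporosis) sit below the 3.5%
#' retention threshold in every subgroup, so a typical realisation retains
#' 14 diseases and 91 candidate pairs.
#'
#' @param seed Integer seed stored in the spec.
#' @return A [cohort_spec()].
#' @export
copd_cohort_spec <- function(seed = 1L) {
  prev <- c(AHT = 0.510, T2DM = 0.194, DLP = 0.570, SAHS = 0.134,
            Obesity = 0.359, Underweight = 0.024, AF = 0.136, IHD = 0.116,
            HF = 0.127, CVA = 0.063, PAD = 0.103, CKD = 0.055,
            Neoplasia = 0.063, Osteoporosis = 0.020, HeavySmoker = 0.398,
            MoodDisorder = 0.106)
  miss <- c(AHT = 502 / 1726, T2DM = 0, DLP = 1009 / 1726, SAHS = 0,
            Obesity = 26 / 1726, Underweight = 26 / 1726, AF = 0, IHD = 0,
            HF = 0, CVA = 0, PAD = 0, CKD = 1 / 1726, Neoplasia = 0,
            Osteoporosis = 0, HeavySmoker = 87 / 1726, MoodDisorder = 0)
  cohort_spec(
    n_subjects = 1726L,
    prevalences = prev,
    cb_fraction = 0.52, ex_fraction = 0.242,
    stratum_mean_phi = list(cb = c(0.098, 0.050), ex = c(0.082, 0.072)),
    missing_rate = miss,
    seed = seed)
}
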