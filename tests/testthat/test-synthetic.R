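test_that("feasible phi bounds match a brute-force grid over 2x2 joints", {
  expect_equal(unname(phi_feasible_bounds(0.5, 0.5)), c(-1, 1))
  expect_equal(unname(phi_feasible_bounds(0.3, 0.3)["upper"]), 1)

  # oracle: exhaustive grid over valid joint probabilities C
  grid_bounds <- function(p_i, p_j) {
    C <- seq(max(0, p_i + p_j - 1), min(p_i, p_j), length.out = 20001)
    phi <- (C - p_i * p_j) / sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
    c(min(phi), max(phi))
  }
  for (pp in list(c(0.1, 0.5), c(0.024, 0.51), c(0.3, 0.7), c(0.05, 0.05))) {
    expect_equal(unname(phi_feasible_bounds(pp[1], pp[2])),
                 grid_bounds(pp[1], pp[2]), tolerance = 1e-9)
  }
})

test_that("orthant probability agrees with independent 2-D quadrature", {
  # closed form at median thresholds: P = 1/4 + asin(rho)/(2*pi)
  for (rho in c(-0.8, -0.3, 0, 0.5, 0.9))
    expect_equal(bvn_upper_prob(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
                 tolerance = 1e-10)

  skip_if_not_installed("pracma")
  quad_oracle <- function(h, k, rho) {
    f <- function(x, y) {
      z <- (x^2 - 2 * rho * x * y + y^2) / (1 - rho^2)
      exp(-z / 2) / (2 * pi * sqrt(1 - rho^2))
    }
    pracma::integral2(f, h, 8.5, k, 8.5, reltol = 1e-11)$Q
  }
  # tolerance set by the 2-D quadrature oracle's own accuracy
  for (h in c(-1, 0, 1.3)) for (k in c(-0.5, 0.8)) for (rho in c(-0.6, 0.2, 0.7))
    expect_equal(bvn_upper_prob(h, k, rho), quad_oracle(h, k, rho),
                 tolerance = 1e-7)
})

test_that("latent-correlation solver inverts the thresholding map", {
  # independence maps to zero latent correlation
  expect_identical(solve_latent_correlation(0.3, 0.6, 0), 0)
  # closed-form check: p = 0.5, rho = 0.5 gives C = 1/3, phi = 1/3
  expect_equal(solve_latent_correlation(0.5, 0.5, 1 / 3), 0.5,
               tolerance = 1e-7)
  # comonotone limit for equal margins
  expect_gt(solve_latent_correlation(0.4, 0.4, 0.999), 0.99)
  # infeasible target reports the feasible interval
  expect_error(solve_latent_correlation(0.1, 0.5, 0.9), "feasible interval")

  # grid: solved rho reproduces the target orthant probability to 1e-6
  for (p_i in c(0.1, 0.35, 0.6)) for (p_j in c(0.2, 0.5)) {
    b <- phi_feasible_bounds(p_i, p_j)
    for (phi in c(0.8 * b[["lower"]], -0.1, 0.15, 0.8 * b[["upper"]])) {
      rho <- solve_latent_correlation(p_i, p_j, phi)
      Ct <- p_i * p_j + phi * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
      expect_equal(bvn_upper_prob(qnorm(1 - p_i), qnorm(1 - p_j), rho), Ct,
                   tolerance = 1e-6)
    }
  }
})

test_that("spec construction validates phi matrices and feasibility", {
  expect_error(cohort_spec(100, c(A = 0.3, B = 0.4),
                           target_phi = matrix(c(1, 0.2, 0.3, 1), 2)),
               "symmetric")
  expect_error(cohort_spec(100, c(A = 0.05, B = 0.9),
                           target_phi = matrix(c(1, 0.9, 0.9, 1), 2)),
               "outside feasible")
  expect_error(cohort_spec(100, c(A = 0, B = 0.4)), "prevalences")
  s <- cohort_spec(100, c(A = 0.3, B = 0.4),
                   target_phi = matrix(c(1, 0.25, 0.25, 1), 2), seed = 3)
  expect_s3_class(s, "cohort_spec")
})

test_that("generation is deterministic and respects the seed everywhere", {
  s <- cohort_spec(400, c(A = 0.3, B = 0.2, C = 0.4),
                   target_phi = {
                     m <- diag(3); m[1, 2] <- m[2, 1] <- 0.2; m
                   },
                   missing_rate = 0.05, seed = 9)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$diseases, b$diseases)
  expect_identical(a$cb, b$cb)
  expect_identical(which(is.na(a$diseases)), which(is.na(b$diseases)))
  d <- generate_cohort(s, seed = 10)
  expect_false(identical(a$diseases, d$diseases))
})

test_that("generated margins and pairwise phi converge to the targets", {
  K <- 5
  p <- c(0.1, 0.25, 0.4, 0.5, 0.7)
  names(p) <- sprintf("D%d", 1:K)

  # identity target: all empirical |phi| small at n = 50 000
  s0 <- cohort_spec(50000, p, seed = 21)
  co0 <- generate_cohort(s0)
  ps0 <- pair_stats(co0)
  expect_lt(max(abs(ps0$phi)), 0.02)

  # planted phi = 0.3 between two diseases at p = 0.4
  tp <- diag(2)
  tp[1, 2] <- tp[2, 1] <- 0.3
  s1 <- cohort_spec(50000, c(A = 0.4, B = 0.4), target_phi = tp, seed = 22)
  co1 <- generate_cohort(s1)
  expect_equal(phi_coefficient(pair_counts(co1, "A", "B")), 0.3,
               tolerance = 0.02 / 0.3)

  # marginal prevalences within the 99.99% binomial band at n = 50 000
  v <- validate_cohort(co0, verbose = FALSE)
  expect_true(all(abs(v$prevalence - p) < 4 * sqrt(p * (1 - p) / 50000)))
})

test_that("phi recovery holds on average across seeds", {
  tp <- matrix(0.15, 4, 4); diag(tp) <- 1
  p <- c(A = 0.2, B = 0.3, C = 0.45, D = 0.6)
  s <- cohort_spec(50000, p, target_phi = tp, seed = 1)
  lat <- latent_structure(s)
  errs <- vapply(1:20, function(r) {
    co <- generate_cohort(s, seed = r, latent = lat)
    mean(abs(pair_stats(co)$phi - 0.15))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("jointly unattainable pairwise targets are projected or refused", {
  # strong +/+/- triangle: pairwise-feasible but jointly non-PSD
  tp <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  s <- cohort_spec(500, c(A = 0.5, B = 0.5, C = 0.5), target_phi = tp)
  expect_error(latent_structure(s), "jointly unattainable")

  tp2 <- matrix(c(1, 0.34, -0.34, 0.34, 1, 0.34, -0.34, 0.34, 1), 3)
  s2 <- cohort_spec(500, c(A = 0.5, B = 0.5, C = 0.5), target_phi = tp2)
  expect_warning(lat2 <- latent_structure(s2), "projected")
  expect_s3_class(generate_cohort(s2, latent = lat2), "cohort_table")
})

test_that("the COPD-scale spec plants the documented study conditions", {
  s <- copd_cohort_spec(seed = 4)
  expect_length(s$disease_names, 16L)
  expect_equal(s$n_subjects, 1726L)
  expect_equal(s$cb_fraction, 0.52)
  expect_equal(s$ex_fraction, 0.242)
  expect_equal(unname(s$prevalences[c("AHT", "Obesity", "AF", "Underweight")]),
               c(0.510, 0.359, 0.136, 0.024))
  # the additive cell decomposition preserves both between-group gaps
  cells <- vapply(s$cell_phi, function(m) m[1, 2], numeric(1))
  expect_equal(unname(cells["CB-Ex-"] - cells["CB+Ex-"]), 0.098 - 0.050)
  expect_equal(unname(cells["CB-Ex-"] - cells["CB-Ex+"]), 0.082 - 0.072)
  # pooled stratum phi implied by cell weights stays near the planted means
  f <- s$cb_fraction; g <- s$ex_fraction
  pooled_cb_neg <- (1 - g) * cells["CB-Ex-"] + g * cells["CB-Ex+"]
  expect_equal(unname(pooled_cb_neg), 0.098, tolerance = 0.05)
  # simulate() returns replicate cohorts deterministically
  reps <- simulate(cohort_spec(50, c(A = 0.4, B = 0.3), seed = 2), nsim = 2)
  expect_length(reps, 2L)
  expect_identical(reps[[1]]$diseases,
                   simulate(cohort_spec(50, c(A = 0.4, B = 0.3), seed = 2),
                            nsim = 2)[[1]]$diseases)
})
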