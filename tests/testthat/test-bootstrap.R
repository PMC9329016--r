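test_that("bootstrap results are bit-identical under a fixed seed", {
  co <- random_cohort(300, c(0.3, 0.2, 0.4), seed = 2)
  cfg <- boot_config(n_resamples = 50, resample_size = 100, seed = 77)
  a <- bootstrap_pairs(co, config = cfg)
  b <- bootstrap_pairs(co, config = cfg)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$draws, b$draws)
  expect_identical(a$prevalence, b$prevalence)
  # different labels draw different streams
  c2 <- bootstrap_pairs(co, config = cfg, label = "other")
  expect_false(identical(a$draws, c2$draws))
  expect_error(bootstrap_pairs(co, config = boot_config(resample_size = 1)),
               "resample_size")
})

test_that("identical disease columns give mean phi 1; summaries are coherent", {
  set.seed(8)
  x <- rbinom(150, 1, 0.4)
  co <- make_cohort(cbind(A = x, B = x, C = rbinom(150, 1, 0.3)))
  res <- bootstrap_pairs(co, config = boot_config(n_resamples = 200, seed = 1))
  ab <- res$pairs[res$pairs$disease_i == "A" & res$pairs$disease_j == "B", ]
  expect_equal(ab$mean_phi, 1)
  expect_equal(ab$phi_p025, 1)
  # order: lower percentile <= mean <= upper percentile, all within [-1, 1]
  ok <- !is.na(res$pairs$mean_phi)
  expect_true(all(res$pairs$phi_p025[ok] <= res$pairs$mean_phi[ok] + 1e-12))
  expect_true(all(res$pairs$mean_phi[ok] <= res$pairs$phi_p975[ok] + 1e-12))
  expect_true(all(abs(res$pairs$mean_phi[ok]) <= 1))
  expect_true(all(res$pairs$n_defined <= res$config$n_resamples))
})

test_that("degenerate resample draws are dropped, not scored as zero", {
  # a very rare disease: many resamples contain no case, so n_defined < B
  set.seed(12)
  co <- make_cohort(cbind(A = c(1L, rep(0L, 99)), B = rbinom(100, 1, 0.5)))
  res <- bootstrap_pairs(co, config = boot_config(n_resamples = 400,
                                                  resample_size = 20,
                                                  seed = 5))
  expect_lt(res$pairs$n_defined, 400)
  expect_equal(sum(is.na(res$draws[, 1])), 400 - res$pairs$n_defined)
  # the mean is over defined draws only
  expect_equal(res$pairs$mean_phi, mean(res$draws[, 1], na.rm = TRUE))
})

test_that("mean phi is near zero for independent diseases", {
  co <- random_cohort(5000, rep(0.3, 4), seed = 31)
  res <- bootstrap_pairs(co, config = boot_config(n_resamples = 1000,
                                                  resample_size = 400,
                                                  seed = 2, keep_p = FALSE))
  expect_lt(max(abs(res$pairs$mean_phi)), 0.05)
})

test_that("bootstrap mean phi converges to the pooled-sample phi", {
  co <- random_cohort(800, c(0.35, 0.45), seed = 14)
  pooled <- phi_coefficient(pair_counts(co, "D01", "D02"))
  res <- bootstrap_pairs(co, config = boot_config(n_resamples = 20000,
                                                  seed = 3, keep_p = FALSE,
                                                  keep_draws = FALSE))
  expect_equal(res$pairs$mean_phi, pooled, tolerance = 0.005 / abs(pooled))
})

test_that("per-resample p-values combine the chi-square and Fisher paths", {
  co <- random_cohort(500, c(0.4, 0.05), seed = 6)
  res <- bootstrap_pairs(co, config = boot_config(n_resamples = 100,
                                                  resample_size = 60,
                                                  seed = 4))
  expect_true(is.finite(res$pairs$mean_p))
  expect_true(res$pairs$mean_p >= 0 && res$pairs$mean_p <= 1)
  # RR summary present and positive
  expect_gt(res$pairs$mean_rr, 0)
})

test_that("edge rule: percentile strictly above zero gates significance", {
  set.seed(40)
  x <- rbinom(400, 1, 0.4)
  y <- ifelse(runif(400) < 0.6, x, rbinom(400, 1, 0.4)) # strongly associated
  co <- make_cohort(cbind(A = x, B = as.integer(y), C = rbinom(400, 1, 0.3)))
  res <- bootstrap_pairs(co, config = boot_config(n_resamples = 500, seed = 9))
  ed <- significant_edges(res)
  expect_true(all(ed$phi_p025 > 0))
  expect_true(any(ed$disease_i == "A" & ed$disease_j == "B"))
  # symmetric-about-zero distribution is never significant
  ind <- res$pairs[res$pairs$disease_i == "A" & res$pairs$disease_j == "C", ]
  expect_false(nrow(ed[ed$disease_i == "A" & ed$disease_j == "C", ]) > 0 &&
                 ind$phi_p025 <= 0)
})

test_that("density is the mean over all pairs and connectivity matches hand arithmetic", {
  res <- structure(list(
    pairs = data.frame(disease_i = c("A", "A", "B"),
                       disease_j = c("B", "C", "C"),
                       mean_phi = c(0.4, 0.2, 0),
                       phi_p025 = c(0.1, 0.05, -0.1),
                       phi_p975 = c(0.6, 0.4, 0.1),
                       n_defined = 100, mean_rr = 1, mean_p = 0.5),
    draws = NULL, prevalence = c(A = 0.3, B = 0.3, C = 0.3),
    n_subjects = 100, label = "toy", diseases = c("A", "B", "C"),
    config = boot_config(n_resamples = 100)), class = "bootstrap_result")
  expect_equal(network_density(res), mean(c(0.4, 0.2, 0)))
  expect_equal(node_connectivity(res),
               c(A = 0.3, B = 0.2, C = 0.1))
  expect_equal(node_connectivity(res, mode = "sum"),
               c(A = 0.6, B = 0.4, C = 0.2))
  # permutation equivariance under relabelling
  res2 <- res
  relab <- c(A = "C", B = "A", C = "B")
  res2$pairs$disease_i <- unname(relab[res2$pairs$disease_i])
  res2$pairs$disease_j <- unname(relab[res2$pairs$disease_j])
  res2$diseases <- c("C", "A", "B")
  c1 <- node_connectivity(res)
  c2 <- node_connectivity(res2)
  expect_equal(unname(c2[relab[names(c1)]]), unname(c1))
})

test_that("connectivity overlap distinguishes planted contrasts and is symmetric", {
  tp <- matrix(0.3, 4, 4); diag(tp) <- 1
  p <- rep(0.35, 4); names(p) <- LETTERS[1:4]
  s_hi <- cohort_spec(2000, p, target_phi = tp, seed = 1)
  s_lo <- cohort_spec(2000, p, seed = 2) # independent
  cfg <- function(seed) boot_config(n_resamples = 400, seed = seed,
                                    keep_p = FALSE)
  r_hi <- bootstrap_pairs(generate_cohort(s_hi), config = cfg(1), label = "hi")
  r_lo <- bootstrap_pairs(generate_cohort(s_lo), config = cfg(1), label = "lo")
  ov <- connectivity_overlap(r_hi, r_lo, "A")
  expect_false(ov$overlap)
  # identical strata overlap
  ov_same <- connectivity_overlap(r_hi, r_hi, "A")
  expect_true(ov_same$overlap)
  # symmetry of the report
  ov2 <- connectivity_overlap(r_lo, r_hi, "A")
  expect_identical(ov$overlap, ov2$overlap)
  expect_equal(ov$interval_a, ov2$interval_b)
  expect_error(connectivity_overlap(r_hi, r_lo, "Z"), "absent")
})
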