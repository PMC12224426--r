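test_that("permutation streams are seeded, uniform, and leave the RNG alone", {
  expect_identical(permutation_stream(10, 20, seed = 3),
                   permutation_stream(10, 20, seed = 3))
  expect_false(identical(permutation_stream(10, 20, seed = 3),
                         permutation_stream(10, 20, seed = 4)))
  # caller RNG state is untouched
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(permutation_stream(5, 5, seed = 1)); x2 <- rnorm(3)
  expect_identical(x1, x2)
  # each of the 3! permutations appears with frequency ~ 1/6
  P <- permutation_stream(3, 6000, seed = 2)
  counts <- table(apply(P, 1, paste, collapse = ""))
  expect_equal(length(counts), 6L)
  chisq <- sum((counts - 1000)^2 / 1000)
  expect_lt(chisq, qchisq(0.999, df = 5))
})

test_that("permuted score statistics match brute-force recomputation", {
  geom <- line3_geometry()
  nb <- build_neighborhoods(geom, c(0, 2))
  K <- unname(kinship_test_retest(c("a", "a", "b", "b")))
  set.seed(51)
  Delta <- matrix(rnorm(12), 4, 3)
  pn <- suppressWarnings(permutation_null(Delta, K, nb, B = 5, seed = 2))
  for (b in 1:5) {
    Dp <- Delta[pn$perms[b, ], ]
    for (v in 1:3) {
      U_b <- brute_quadform(Dp[, v], K)
      k0 <- which(nb$radii == 0)
      expect_equal(pn$S_perm[(k0 - 1) * 3 + v, b], U_b, tolerance = 1e-10)
    }
    # shuffling preserves the residual row multiset
    expect_setequal(pn$perms[b, ], 1:4)
  }
  # identity permutation reproduces the observed statistic
  expect_equal(pn$U, as.numeric(score_statistics(Delta, K)))
})

test_that("exchangeable kernels degenerate to zero permutation variance", {
  geom <- line3_geometry()
  nb <- build_neighborhoods(geom, 0)
  Delta <- matrix(rnorm(12), 4, 3)
  pn <- permutation_null(Delta, diag(4), nb, B = 60, seed = 1)
  # row permutations leave sum d_i^2 unchanged -> flagged as degenerate
  expect_error(standardize_sums(pn$S_obs, pn$S_perm),
               "zero permutation variance")
})

test_that("the FWER threshold is the exact-level order statistic", {
  # B = 20: ceil(0.95 * 21) = 20th value; rejecting above it spends
  # 1/21 < alpha of the exchangeable ranks
  expect_equal(fwer_threshold(1:20, alpha = 0.05), 20)
  set.seed(52)
  x <- rnorm(100)
  expect_equal(fwer_threshold(x, alpha = 0.05), sort(x)[96])
  expect_equal(fwer_threshold(x, alpha = 0.999), sort(x)[1])
  expect_error(fwer_threshold(x, alpha = 0), "alpha")
  expect_error(fwer_threshold(x, alpha = 1), "alpha")
  # rejection rule and permutation p-value pick the same exchangeable ranks:
  # T > t_alpha  <=>  (1 + #{T_perm >= T}) / (B + 1) <= alpha
  for (Tobs in seq(-3, 3, by = 0.25)) {
    expect_identical(Tobs > fwer_threshold(x, 0.05),
                     (1 + sum(x >= Tobs)) / 101 <= 0.05)
  }
})

test_that("the non-spatial variant with radius zero is exactly massive", {
  sc <- simulation_scenario("test_retest", n_units = 8, theta2 = 0.5,
                            mesh_size = 5)
  sim <- simulate_dataset(sc, seed = 4)
  r1 <- run_cleanv(sim$Y, NULL, sim$geometry, sim$K, radii = 0, B = 100,
                   seed = 6, variant = "no_spatial")
  r2 <- run_cleanv(sim$Y, NULL, sim$geometry, sim$K, radii = 0:5, B = 100,
                   seed = 6, variant = "massive")
  expect_equal(r1$Tv, r2$Tv, tolerance = 1e-12)
  expect_equal(r1$T_perm, r2$T_perm, tolerance = 1e-12)
  expect_identical(r1$significant, r2$significant)
})

test_that("with no true spatial noise the full pipeline approaches massive", {
  sc <- simulation_scenario("test_retest", n_units = 50, theta2 = 0.5,
                            sigma2 = 0, mesh_size = 7)
  sim <- simulate_dataset(sc, seed = 8)
  rf <- run_cleanv(sim$Y, NULL, sim$geometry, sim$K, radii = 0, B = 200,
                   seed = 9, variant = "full")
  rm_ <- run_cleanv(sim$Y, NULL, sim$geometry, sim$K, radii = 0, B = 200,
                    seed = 9, variant = "massive")
  expect_lt(rf$params$sigma2, 0.1)
  expect_lt(max(abs(rf$Tv - rm_$Tv)), 0.05)
})

test_that("seeded runs are fully reproducible and internally consistent", {
  sc <- simulation_scenario("twin", n_units = 10, theta2 = 1, mesh_size = 5)
  sim <- simulate_dataset(sc, seed = 11)
  r1 <- run_cleanv(sim$Y, NULL, sim$geometry, sim$K, radii = 0:3, B = 100,
                   seed = 12)
  r2 <- run_cleanv(sim$Y, NULL, sim$geometry, sim$K, radii = 0:3, B = 100,
                   seed = 12)
  expect_identical(r1, r2)
  # localization re-derives from the stored map and threshold
  expect_identical(r1$significant,
                   which(!is.na(r1$Tv) & r1$Tv > r1$t_alpha))
  expect_equal(r1$T, max(r1$Tv, na.rm = TRUE))
  expect_equal(r1$T, max(r1$Tr, na.rm = TRUE))
  expect_true(all(r1$Tv >= r1$Tr[1, ], na.rm = TRUE))
  # global decision and p-value agree away from the rank boundary
  if (r1$T > r1$t_alpha) expect_lte(r1$p_global, r1$config$alpha + 1 / 101)
  if (r1$T < r1$t_alpha) expect_gt(r1$p_global, r1$config$alpha)
  expect_equal(r1$p_global,
               (1 + sum(r1$T_perm >= r1$T)) / (r1$config$B + 1))
})

test_that("masked vertices are excluded end to end", {
  sc <- simulation_scenario("test_retest", n_units = 8, theta2 = 1,
                            mesh_size = 5)
  sim <- simulate_dataset(sc, seed = 13)
  geom <- sim$geometry
  geom$mask[1:5] <- FALSE
  geom$D <- NULL  # force recomputation under the mask
  res <- run_cleanv(sim$Y, NULL, geom, sim$K, radii = 0:3, B = 100, seed = 2)
  expect_true(all(is.na(res$Tv[1:5])))
  expect_false(any(res$significant %in% 1:5))
})

test_that("method-of-moments effect sizes track the generating ratio", {
  # clipping the ratio at zero leaves a small positive floor of order
  # E[max(N(0, 1/n_pairs^0.5), 0)], so use enough pairs to sit below 0.05
  sc0 <- simulation_scenario("null", n_units = 250, mesh_size = 5, sigma2 = 0)
  sim0 <- simulate_dataset(sc0, seed = 21)
  es0 <- estimate_effect_size(sim0$Y, NULL, sim0$K)
  expect_lt(mean(es0$ratio), 0.05)

  # theta2 = tau2 with no spatial noise -> ratio 0.5 on the signal region
  sc1 <- simulation_scenario("test_retest", n_units = 150, theta2 = 1,
                             sigma2 = 0, tau2 = 1, mesh_size = 5,
                             signal_frac = 1)
  sim1 <- simulate_dataset(sc1, seed = 22)
  es1 <- estimate_effect_size(sim1$Y, NULL, sim1$K)
  expect_equal(mean(es1$ratio), 0.5, tolerance = 0.06)

  # duplicated test-retest images: all variance is subject-level
  Yd <- matrix(rnorm(5 * 6), 5, 6)[rep(1:5, each = 2), ]
  Kd <- kinship_test_retest(rep(1:5, each = 2))
  esd <- estimate_effect_size(Yd, NULL, Kd)
  expect_equal(esd$ratio, rep(1, 6), tolerance = 1e-10)

  expect_error(estimate_effect_size(Yd, NULL, diag(10)), "no related")
})
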