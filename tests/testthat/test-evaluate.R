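# Metrics and statistical tests against independent oracles.

test_that("grid matching picks the nearest month with earlier-tie rule", {
  grid <- tibble::tibble(participant_id = "P1", month = 1:24, horizon = 1:24,
                         p_cn = 0.5, p_mci = 0.3, p_dem = 0.2,
                         mmse = 26, ventricle_icv = 0.02)
  tv <- make_visits(month = c(10.4, 10.5, 23), mmse = c(25, 24, 22))
  pairs <- match_forecasts(grid, tv)
  expect_equal(pairs$grid_month, c(10, 10, 23))
  # beyond-horizon visits are dropped and counted
  tv2 <- make_visits(month = c(5, 30), mmse = c(25, 20))
  pairs2 <- match_forecasts(grid, tv2)
  expect_equal(nrow(pairs2), 1)
  expect_equal(attr(pairs2, "n_beyond_horizon"), 1L)
  expect_error(match_forecasts(grid[0, ], tv), "empty")
})

test_that("pooled mAUC matches the O(n^2) pairwise oracle", {
  set.seed(10)
  for (n in c(20, 60, 200)) {
    probs <- matrix(runif(n * 3), ncol = 3)
    probs <- probs / rowSums(probs)
    truth <- sample(c("CN", "MCI", "DEM"), n, replace = TRUE)
    expect_equal(mauc(probs, truth), oracle_mauc(probs, truth),
                 tolerance = 1e-12)
  }
})

test_that("mAUC hits the perfect and chance anchors and the worked set", {
  truth <- c("CN", "CN", "MCI", "MCI", "DEM", "DEM")
  perfect <- matrix(0, 6, 3)
  perfect[cbind(1:6, c(1, 1, 2, 2, 3, 3))] <- 1
  expect_equal(mauc(perfect, truth), 1.0)

  constant <- matrix(1 / 3, 6, 3)
  expect_equal(mauc(constant, truth), 0.5)

  probs <- rbind(c(.7, .2, .1), c(.6, .3, .1), c(.2, .5, .3),
                 c(.3, .4, .3), c(.1, .3, .6), c(.2, .2, .6))
  expect_equal(mauc(probs, truth), 1.0)
  swapped <- c("DEM", "DEM", "MCI", "MCI", "CN", "CN")
  expect_lt(mauc(probs, swapped), 0.5)
})

test_that("mAUC is invariant to monotone transforms and skips absent classes", {
  set.seed(11)
  probs <- matrix(runif(90), ncol = 3)
  truth <- sample(c("CN", "MCI", "DEM"), 30, replace = TRUE)
  warped <- cbind(exp(probs[, 1]), probs[, 2]^3 + 1, log1p(probs[, 3]))
  expect_equal(mauc(probs, truth), mauc(warped, truth))

  two_class <- sample(c("CN", "MCI"), 30, replace = TRUE)
  expect_message(m2 <- mauc(probs, two_class), "DEM")
  expect_true(m2 >= 0 && m2 <= 1)
  expect_error(suppressMessages(mauc(probs, rep("CN", 30))), "no class")
})

test_that("per-participant errors average within participants first", {
  pairs <- tibble::tibble(
    participant_id = c("A", "A", "B"),
    mmse = c(25, 27, 20), true_mmse = c(26, 24, 20),
    ventricle_icv = c(0.02, 0.02, 0.03),
    true_ventricle_icv = c(0.021, NA, 0.03))
  r <- mae_by_participant(pairs, "mmse")
  expect_equal(r$per_participant$mae, c(2, 0))   # A: (1+3)/2; B: 0
  expect_equal(r$mae, 1)
  expect_equal(r$per_participant$rmse[1], sqrt(5))
  rv <- mae_by_participant(pairs, "ventricle_icv")
  expect_equal(rv$n_participants, 2)
  # a participant with no observed truth is excluded and counted
  pairs$true_ventricle_icv <- c(NA, NA, 0.03)
  rv2 <- mae_by_participant(pairs, "ventricle_icv")
  expect_equal(rv2$n_excluded, 1)
})

test_that("corrected resampled t matches an independent transcription", {
  set.seed(12)
  d <- rnorm(20)
  r <- corrected_resampled_ttest(d, rho = 1 / 19)
  o <- oracle_corrected_t(d, 1 / 19)
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)

  # rho = 0 recovers the classical one-sample t-test
  r0 <- corrected_resampled_ttest(d, rho = 0)
  classical <- t.test(d)
  expect_equal(r0$statistic, unname(classical$statistic), tolerance = 1e-12)
  expect_equal(r0$p_value, classical$p.value, tolerance = 1e-12)

  expect_equal(corrected_resampled_ttest(rep(0, 5))$p_value, 1)
  expect_warning(rz <- corrected_resampled_ttest(rep(0.3, 5)), "zero variance")
  expect_equal(rz$p_value, 0)
  expect_equal(tidy(r)$p.value, r$p_value)
})

test_that("the mAUC permutation test behaves at its boundaries", {
  set.seed(13)
  n <- 60
  probs <- matrix(runif(n * 3), ncol = 3); probs <- probs / rowSums(probs)
  truth <- sample(c("CN", "MCI", "DEM"), n, replace = TRUE)
  same <- permutation_test_mauc(probs, probs, truth, n_perm = 50, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  other <- matrix(runif(n * 3), ncol = 3); other <- other / rowSums(other)
  r <- permutation_test_mauc(probs, other, truth, n_perm = 99, seed = 2)
  expect_gte(r$p_value, 1 / 100)
  expect_lte(r$p_value, 1)
  expect_error(permutation_test_mauc(probs, other[1:10, ], truth),
               "do not match")
})

test_that("BH step-up flags match a hand enumeration", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  # hand-executed step-up at q = 0.05: thresholds i/10 * 0.05 are
  # 0.005, 0.010, 0.015, ...; the largest i with p_(i) <= threshold is 2
  expect_equal(fdr_bh(p, 0.05), c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_false(any(fdr_bh(rep(1, 4), 0.05)))
  expect_true(fdr_bh(0.01, 0.05))
})

test_that("horizon bins close on the right at 12-month multiples", {
  expect_equal(bin_by_horizon(60, 70), 1)   # 10-month gap: 1 year out
  expect_equal(bin_by_horizon(0, 12), 1)
  expect_equal(bin_by_horizon(0, 12.1), 2)
  expect_equal(bin_by_horizon(0, 80), 6)    # capped
  expect_error(bin_by_horizon(10, 10), "after")
})

test_that("subgroups follow the last observed input diagnosis", {
  inp <- dplyr::bind_rows(
    make_visits("A", month = c(0, 6), diagnosis = c("CN", "MCI")),
    make_visits("B", month = c(0, 6), diagnosis = c(NA, NA)),
    make_visits("C", month = c(0, 6, 12), diagnosis = c("MCI", NA, "DEM")))
  sg <- subgroup_by_last_dx(inp)
  expect_equal(sg$subgroup[sg$participant_id == "A"], "MCI")
  expect_equal(sg$subgroup[sg$participant_id == "C"], "DEM")
  expect_false("B" %in% sg$participant_id)
  expect_equal(attr(sg, "n_excluded"), 1L)
})

test_that("modality ablation blanks only its block on input visits", {
  co <- dplyr::bind_rows(
    make_visits("A", month = c(0, 6, 12, 18), mmse = 28, cdr_global = 0.5,
                diagnosis = "MCI", hippocampus = 7e3, ventricle = 3e4,
                icv = 1.5e6))
  abl <- ablate_modality(co, "mri")
  # input half = first 2 visits
  expect_true(all(is.na(abl$hippocampus[1:2])))
  expect_true(all(is.na(abl$icv[1:2])))
  expect_false(anyNA(abl$hippocampus[3:4]))
  expect_equal(abl$mmse, co$mmse)
  expect_equal(abl$diagnosis, co$diagnosis)
  expect_identical(ablate_modality(co, "none"), co)
  expect_error(ablate_modality(co, "genetics"), "arg")
})

test_that("ablation deltas are signed towards degradation", {
  reports <- tibble::tibble(
    scenario = c("full", "mri", "cognitive"),
    mauc = c(0.9, 0.8, 0.85),
    mmse_mae = c(1.0, 1.5, 2.0),
    ventricle_mae = c(0.001, 0.003, 0.001))
  d <- feature_importance_by_ablation(reports)
  expect_equal(nrow(d), 6)  # one row per (modality, metric)
  expect_equal(d$delta[d$modality == "mri" & d$metric == "mauc"], 0.1)
  expect_equal(d$delta[d$modality == "cognitive" & d$metric == "mmse_mae"], 1.0)
  same <- feature_importance_by_ablation(
    tibble::tibble(scenario = c("full", "mri"), mauc = 0.9, mmse_mae = 1,
                   ventricle_mae = 0.01))
  expect_true(all(same$delta == 0))
})
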