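# Forecaster bundles: window routing, CDR conversion, the network's masked
# loss and determinism, carry-forward behaviour.

test_that("window routing follows the per-target interval tables", {
  w <- l2c_windows()
  expect_equal(sum(vapply(w, nrow, integer(1))), 15)
  expect_equal(select_window(10, "mmse", w), 2L)       # 9-15
  expect_equal(select_window(70, "diagnosis", w), 6L)  # >60
  expect_equal(select_window(45, "mmse", w), 4L)       # hole -> 27-39 model
  expect_equal(select_window(54, "mmse", w), 4L)       # hole is (39, 54]
  expect_equal(select_window(55, "mmse", w), 5L)
  expect_equal(select_window(0, "ventricle", w), 1L)
  expect_equal(select_window(30, "ventricle", w), 4L)  # closed on the left
  expect_true(is.na(select_window(NA, "mmse", w)))
  expect_error(select_window(-1, "mmse", w), "negative")
  # every non-hole gap belongs to exactly one window
  gaps <- seq(0, 119.5, by = 0.5)
  for (tg in c("diagnosis", "ventricle")) {
    idx <- select_window(gaps, tg, w)
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("CDR-to-diagnosis conversion matches the interpolation anchors", {
  expect_equal(as.numeric(cdr_to_diag_probs(0.1)), c(0.8, 0.2, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(cdr_to_diag_probs(0.6)), c(0, 0.8, 0.2),
               tolerance = 1e-12)
  expect_equal(as.numeric(cdr_to_diag_probs(0)), c(1, 0, 0))
  expect_equal(as.numeric(cdr_to_diag_probs(2)), c(0, 0, 1))
  expect_equal(as.numeric(cdr_to_diag_probs(-0.3)), c(1, 0, 0))  # clipped
  # continuous, bounded, sums to one along the whole range
  grid <- cdr_to_diag_probs(seq(0, 3, by = 0.01))
  expect_true(all(abs(rowSums(grid) - 1) < 1e-9))
  expect_true(all(grid >= 0 & grid <= 1))
  expect_true(all(abs(diff(grid[, 1])) <= 0.021))  # no jumps
})

test_that("masked loss terms contribute zero for unobserved targets", {
  out <- matrix(c(1, 0, -1, 0.3, -0.2), nrow = 1)
  with_all <- fnn_loss_grad(out, dx_idx = 1L, y_mmse = 0.5, y_vent = 0.1)
  no_mmse <- fnn_loss_grad(out, dx_idx = 1L, y_mmse = NA, y_vent = 0.1)
  expect_equal(with_all$loss - no_mmse$loss, abs(0.3 - 0.5))
  expect_equal(no_mmse$grad[1, 4], 0)
  only_dx <- fnn_loss_grad(out, dx_idx = 2L, y_mmse = NA, y_vent = NA)
  expect_equal(only_dx$grad[1, 4:5], c(0, 0))
  p <- exp(out[1, 1:3]) / sum(exp(out[1, 1:3]))
  expect_equal(only_dx$loss, -log(p[2]))
})

test_that("network training is deterministic given the seed", {
  co <- small_cohort()
  samp <- l2c_training_samples(co)[1:300, ]
  cfg <- fnn_config(epochs = 3, seed = 42)
  b1 <- train_fnn_bundle(samp, cfg)
  b2 <- train_fnn_bundle(samp, cfg)
  expect_identical(b1$estimators[[1]]$epoch_losses,
                   b2$estimators[[1]]$epoch_losses)
  expect_error(train_fnn(matrix(0, 2, 3), c(NA, NA), c(NA, NA), c(NA, NA)),
               "no sample")
})

test_that("network predictions respect softmax, clipping and batching", {
  co <- small_cohort()
  samp <- l2c_training_samples(co)
  bundle <- train_fnn_bundle(samp[1:400, ], fnn_config(epochs = 5, seed = 7))
  pred <- predict_bundle(bundle, samp[401:450, ])
  expect_true(all(abs(pred$p_cn + pred$p_mci + pred$p_dem - 1) < 1e-6))
  expect_true(all(pred$mmse >= 0 & pred$mmse <= 30))
  expect_true(all(pred$ventricle_icv >= 0))
  # batch prediction equals row-by-row prediction
  one_by_one <- dplyr::bind_rows(lapply(401:410, function(i)
    predict_bundle(bundle, samp[i, ])))
  expect_equal(as.data.frame(one_by_one),
               as.data.frame(pred[1:10, ]), tolerance = 1e-10)
})

test_that("bundle cardinalities are enforced on construction", {
  co <- small_cohort()
  samp <- l2c_training_samples(co)
  par <- xgb_params(nrounds = 10)
  b_nw <- train_xgb(samp, par, seed = 1)
  expect_equal(glance(b_nw)$n_estimators, 3)
  b_w <- train_xgb(samp, par, windows = l2c_windows(), seed = 1)
  expect_equal(glance(b_w)$n_estimators, 15)
  expect_equal(nrow(tidy(b_w)), 15)
  expect_error(new_bundle("xgb_nw", list(1, 2)), "must hold 3")

  # window assignment partitions the covered samples per target
  gaps <- samp$time_since_mr_mmse
  idx <- select_window(gaps, "mmse")
  covered <- !is.na(idx)
  expect_equal(sum(table(idx)), sum(covered))
  hole <- !is.na(gaps) & gaps > 39 & gaps <= 54
  expect_true(all(idx[hole] == 4L))
})

test_that("an empty training window is a named error", {
  v <- dplyr::bind_rows(lapply(1:12, function(i)
    make_visits(sprintf("P%02d", i), month = c(0, 3),
                mmse = c(28, 27), diagnosis = "CN",
                ventricle = 3e4, icv = 1.5e6)))
  samp <- l2c_training_samples(v)  # all gaps ~3 months: long windows empty
  expect_error(train_xgb(samp, xgb_params(nrounds = 5),
                         windows = l2c_windows(), seed = 1),
               "window")
})

test_that("carry-forward repeats the last observation with sane fallbacks", {
  co <- small_cohort()
  samp <- l2c_training_samples(co)
  cf <- train_carry_forward(samp)
  feats <- assemble_features(
    make_visits(month = c(0, 6), mmse = c(28, 27), diagnosis = c("CN", "MCI"),
                ventricle = 3e4, icv = 1.5e6), tf = 30)
  p <- predict_bundle(cf, feats)
  expect_equal(c(p$p_cn, p$p_mci, p$p_dem), c(0, 1, 0))
  expect_equal(p$mmse, 27)
  expect_equal(p$ventricle_icv, 0.02)
  # never-observed targets fall back to uniform probabilities / medians
  empty <- assemble_features(make_visits(month = c(0, 6)), tf = 30)
  p0 <- predict_bundle(cf, empty)
  expect_equal(c(p0$p_cn, p0$p_mci, p0$p_dem), rep(1 / 3, 3))
  expect_equal(p0$mmse, cf$extra$mmse_median)
})

test_that("monthly forecasting fills the grid deterministically", {
  co <- small_cohort()
  samp <- l2c_training_samples(co)
  bundle <- train_xgb(samp, xgb_params(nrounds = 10), seed = 3)
  one <- co[co$participant_id == unique(co$participant_id)[1], ]
  grid <- forecast_monthly(bundle, one, horizon_months = 120)
  expect_equal(nrow(grid), 120)
  expect_equal(diff(grid$month), rep(1, 119))
  grid2 <- forecast_monthly(bundle, one, horizon_months = 120)
  expect_identical(as.data.frame(grid), as.data.frame(grid2))
})

test_that("the windowed variant reports unavailable when never observed", {
  co <- small_cohort()
  samp <- l2c_training_samples(co)
  b_w <- train_xgb(samp, xgb_params(nrounds = 10), windows = l2c_windows(),
                   seed = 2)
  # history without any MMSE observation: MMSE prediction unavailable
  feats <- assemble_features(
    make_visits(month = c(0, 6), diagnosis = c("CN", "MCI"),
                ventricle = 3e4, icv = 1.5e6), tf = 18)
  p <- predict_bundle(b_w, feats)
  expect_true(is.na(p$mmse))
  expect_false(is.na(p$ventricle_icv))
  expect_false(is.na(p$p_dem))
})
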