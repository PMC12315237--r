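# The L2C transformation: temporal summaries, diagnosis features, vector
# assembly and training-sample augmentation.

test_that("continuous temporal summaries match direct evaluation", {
  f <- continuous_features(c(0, 12), c(28, 26), tf = 24)
  expect_equal(f$mr, 26)
  expect_equal(f$time_since_mr, 12)
  expect_equal(f$mr_change, -1 / 6)
  expect_equal(f$low, 26); expect_equal(f$time_since_low, 12)
  expect_equal(f$high, 28); expect_equal(f$time_since_high, 24)

  # single observation: only the change rate is missing
  g <- continuous_features(0, 28, tf = 6)
  expect_equal(g$mr, 28); expect_equal(g$time_since_mr, 6)
  expect_true(is.na(g$mr_change))
  expect_equal(c(g$low, g$high), c(28, 28))

  # constant series: min/max ties resolve to the most recent occurrence
  h <- continuous_features(c(0, 6, 12), c(25, 25, 25), tf = 18)
  expect_equal(h$mr_change, 0)
  expect_equal(c(h$low, h$high), c(25, 25))
  expect_equal(c(h$time_since_low, h$time_since_high), c(6, 6))

  # empty series: all seven missing
  e <- continuous_features(numeric(0), numeric(0), tf = 10)
  expect_true(all(vapply(e, is.na, logical(1))))
  expect_error(continuous_features(c(0, 30), c(28, 26), tf = 24), "precede")
  expect_error(continuous_features(0, Inf, tf = 6), "non-finite")
})

test_that("diagnosis-history features follow the severity order", {
  f <- diagnosis_features(c(0, 12), c("CN", "MCI"), tf = 24)
  expect_equal(f$mr_dx, "MCI"); expect_equal(f$time_since_mr_dx, 12)
  expect_equal(f$best_dx, "CN"); expect_equal(f$time_since_best_dx, 24)
  expect_equal(f$worst_dx, "MCI"); expect_equal(f$time_since_worst_dx, 12)
  expect_equal(f$milder, 1); expect_equal(f$time_since_milder, 24)

  g <- diagnosis_features(c(0, 6, 12), c("CN", "CN", "CN"), tf = 18)
  expect_equal(g$milder, 0)
  expect_equal(g$time_since_milder, 999)

  e <- diagnosis_features(numeric(0), character(0), tf = 10)
  expect_true(all(vapply(e, is.na, logical(1))))
  expect_error(diagnosis_features(0, "AD", tf = 6), "unknown diagnosis")
})

test_that("assembled vectors always carry 64 engineered + 6 covariate fields", {
  expect_length(l2c_feature_names(), 70)
  expect_length(l2c_feature_names(engineered_only = TRUE), 64)

  co <- small_cohort()
  ids <- unique(co$participant_id)
  for (id in ids[1:15]) {
    visits <- co[co$participant_id == id, ]
    m <- nrow(visits)
    vec <- assemble_features(visits, tf = max(visits$month) + 6)
    expect_equal(ncol(vec), 70)
    expect_identical(names(vec), l2c_feature_names())
  }
  expect_error(assemble_features(co[co$participant_id == ids[1], ], tf = 0),
               "after")
})

test_that("the vector is invariant to visit storage order", {
  visits <- make_visits(month = c(0, 7, 13, 20), mmse = c(28, 27, 26, 24),
                        diagnosis = c("CN", "CN", "MCI", "MCI"),
                        ventricle = c(3e4, 3.1e4, 3.3e4, 3.4e4), icv = 1.5e6)
  set.seed(1)
  shuffled <- visits[sample(nrow(visits)), ]
  expect_equal(assemble_features(visits, 30), assemble_features(shuffled, 30))
})

test_that("time-since fields are tf minus an actual visit month (bar sentinel)", {
  visits <- make_visits(month = c(0, 7, 13), mmse = c(28, 27, 26),
                        diagnosis = c("CN", "MCI", "MCI"),
                        ventricle = 3e4, icv = 1.5e6)
  tf <- 25
  vec <- assemble_features(visits, tf)
  ts_cols <- grep("^time_since_", names(vec), value = TRUE)
  for (col in ts_cols) {
    v <- vec[[col]]
    if (is.na(v) || v == 999) next
    expect_true(any(abs((tf - v) - visits$month) < 1e-9), info = col)
  }
  # with a complete history only change-rate fields may be missing
  full <- make_visits(month = c(0, 8), mmse = c(28, 27), cdr_global = 0,
                      diagnosis = "CN", hippocampus = 7e3, fusiform = 1.7e4,
                      midtemp = 2e4, ventricle = 3e4, wholebrain = 1.03e6,
                      icv = 1.5e6, age = c(70, 70.67))
  vec2 <- assemble_features(full, 20)
  missing_cols <- names(vec2)[vapply(vec2, is.na, logical(1))]
  expect_true(all(grepl("^mr_change_", missing_cols)))
  expect_length(missing_cols, 0)  # two observations: change rates computable
})

test_that("time-varying fields alone change between adjacent forecast months", {
  visits <- make_visits(month = c(0, 9), mmse = c(28, 26),
                        diagnosis = c("CN", "MCI"), ventricle = 3e4,
                        icv = 1.5e6, age = c(71, 71.75))
  a <- assemble_features(visits, 20)
  b <- assemble_features(visits, 21)
  changed <- names(a)[vapply(names(a), function(cn)
    !identical(a[[cn]], b[[cn]]), logical(1))]
  time_dep <- c(grep("^time_since_", names(a), value = TRUE),
                "age_at_tf", "months_since_baseline")
  expect_true(all(changed %in% time_dep))
  # sentinel-valued time_since_milder must not drift with tf
  all_cn <- make_visits(month = c(0, 9), diagnosis = "CN")
  expect_equal(assemble_features(all_cn, 20)$time_since_milder, 999)
  expect_equal(assemble_features(all_cn, 21)$time_since_milder, 999)
})

test_that("augmentation enumerates every (prefix, later visit) pair", {
  # m = 4: the six pairs by prefix length
  visits <- make_visits(month = c(0, 6, 12, 18), mmse = c(28, 27, 26, 25))
  samp <- l2c_training_samples(visits, keep_all = TRUE)
  expect_equal(nrow(samp), 6)
  expect_equal(samp$prefix_len, c(1, 1, 1, 2, 2, 3))
  expect_equal(samp$target_visit, c(2, 3, 4, 3, 4, 4))

  # m = 2 gives a single sample
  expect_equal(nrow(l2c_training_samples(make_visits(month = c(0, 6),
                                                     mmse = 28))), 1)

  # brute-force count m(m-1)/2 for m = 2..30
  for (m in c(2, 3, 5, 10, 17, 30)) {
    v <- make_visits(month = seq(0, by = 6, length.out = m), mmse = 25)
    n_pairs <- 0
    for (p in 1:(m - 1)) for (q in (p + 1):m) n_pairs <- n_pairs + 1
    expect_equal(nrow(l2c_training_samples(v, keep_all = TRUE)), n_pairs)
    expect_equal(n_pairs, m * (m - 1) / 2)
  }

  # samples without any observed target are dropped
  v <- make_visits(month = c(0, 6, 12))
  v$mmse <- c(28, NA, 27)
  samp2 <- l2c_training_samples(v)
  expect_true(all(!is.na(samp2$target_mmse)))
  expect_equal(nrow(samp2), 2)  # targets at visits 1..3 observed only at 1,3
})

test_that("the transformation reduces the missing-data fraction", {
  co <- small_cohort()
  raw_cells <- co[, c("mmse", "cdr_global", "diagnosis",
                      paste0(c("hippocampus", "fusiform", "midtemp",
                               "ventricle", "wholebrain"), "_icv"), "icv")]
  raw_missing <- mean(is.na(as.matrix(raw_cells)))
  samp <- l2c_training_samples(co)
  eng <- samp[, l2c_feature_names(engineered_only = TRUE)]
  l2c_missing <- mean(is.na(as.matrix(eng)))
  expect_lt(l2c_missing, raw_missing)
})
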