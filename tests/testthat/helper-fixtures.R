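# Fixture builders and independent oracles shared across tests.

# minimal visit tibble with all cohort columns; unspecified cells missing
make_visits <- function(id = "P1", month, mmse = NA, cdr_global = NA,
                        diagnosis = NA, hippocampus = NA, fusiform = NA,
                        midtemp = NA, ventricle = NA, wholebrain = NA,
                        icv = NA, age = NA, sex = "female",
                        education_years = 16, marital = "married",
                        apoe4_count = 0) {
  n <- length(month)
  tibble::tibble(
    participant_id = rep_len(id, n), month = month,
    age = rep_len(age, n), sex = rep_len(sex, n),
    education_years = rep_len(education_years, n),
    marital = rep_len(marital, n), apoe4_count = rep_len(apoe4_count, n),
    mmse = rep_len(mmse, n), cdr_global = rep_len(cdr_global, n),
    diagnosis = rep_len(as.character(diagnosis), n),
    hippocampus = rep_len(hippocampus, n), fusiform = rep_len(fusiform, n),
    midtemp = rep_len(midtemp, n), ventricle = rep_len(ventricle, n),
    wholebrain = rep_len(wholebrain, n), icv = rep_len(icv, n),
    hippocampus_icv = rep_len(hippocampus, n) / rep_len(icv, n),
    fusiform_icv = rep_len(fusiform, n) / rep_len(icv, n),
    midtemp_icv = rep_len(midtemp, n) / rep_len(icv, n),
    ventricle_icv = rep_len(ventricle, n) / rep_len(icv, n),
    wholebrain_icv = rep_len(wholebrain, n) / rep_len(icv, n))
}

# small simulated cohort cached across tests
small_cohort <- local({
  cache <- NULL
  function(n = 120, seed = 0, ...) {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(n_participants = n, seed = seed, ...))
    }
    cache
  }
})

# O(n^2) pairwise-count one-vs-rest AUC oracle with half-credit ties
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

oracle_mauc <- function(probs, truth) {
  classes <- c("CN", "MCI", "DEM")
  aucs <- c()
  for (k in seq_along(classes)) {
    pos <- truth == classes[k]
    if (any(pos) && any(!pos)) aucs <- c(aucs, oracle_auc(probs[, k], pos))
  }
  mean(aucs)
}

# independent transcription of the overlap-corrected t statistic
oracle_corrected_t <- function(d, rho) {
  k <- length(d)
  dbar <- sum(d) / k
  s2 <- sum((d - dbar)^2) / (k - 1)
  tt <- dbar / sqrt((1 / k + rho) * s2)
  list(t = tt, p = 2 * (1 - stats::pt(abs(tt), k - 1)))
}
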