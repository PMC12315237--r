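# Synthetic longitudinal cohort generator: sigmoidal biomarker trajectories on
# a latent disease clock, irregular visit schedules, per-modality MCAR
# missingness and site presets that shift severity mix and data density.

default_trajectories <- function() {
  list(
    mmse       = trajectory_params(1,       29,      0.35, 10, "decreasing", noise_sd = 1),
    hippocampus = trajectory_params(5000,   7500,    0.35, 6, "decreasing", noise_sd = 150),
    fusiform   = trajectory_params(14000,   18000,   0.30, 7, "decreasing", noise_sd = 400),
    midtemp    = trajectory_params(15500,   20000,   0.30, 7, "decreasing", noise_sd = 400),
    ventricle  = trajectory_params(28000,   65000,   0.35, 7, "increasing", noise_sd = 1500),
    wholebrain = trajectory_params(900000,  1050000, 0.25, 8, "decreasing", noise_sd = 15000)
  )
}

#' Logistic biomarker trajectory parameters
#'
#' @param asymptote_low,asymptote_high Lower/upper plateau of the biomarker.
#' @param slope Logistic steepness per year of disease time (> 0).
#' @param inflection_offset Disease time (years past onset) of the inflection.
#' @param direction `"increasing"` or `"decreasing"` with disease time.
#' @param noise_sd Gaussian measurement noise SD added by the generator.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(asymptote_low, asymptote_high, slope,
                              inflection_offset, direction = "increasing",
                              noise_sd = 0) {
  stopifnot(asymptote_low < asymptote_high, slope > 0,
            direction %in% c("increasing", "decreasing"))
  structure(list(asymptote_low = asymptote_low, asymptote_high = asymptote_high,
                 slope = slope, inflection_offset = inflection_offset,
                 direction = direction, noise_sd = noise_sd),
            class = "trajectory_params")
}

#' Evaluate a logistic biomarker trajectory
#'
#' `low + (high - low) * plogis(slope * (s - offset))` for increasing markers,
#' mirrored for decreasing ones; bounded by the asymptotes, with the midpoint
#' at the inflection offset.
#'
#' @param disease_time Years since latent disease onset (may be negative).
#' @param params A [trajectory_params()] object.
#' @return Numeric biomarker values (noise-free).
#' @export
logistic_value <- function(disease_time, params) {
  sgn <- if (params$direction == "increasing") 1 else -1
  params$asymptote_low + (params$asymptote_high - params$asymptote_low) *
    stats::plogis(sgn * params$slope * (disease_time - params$inflection_offset))
}

site_presets <- function() {
  path <- system.file("extdata", "site_presets.yaml", package = "l2cforecast")
  if (path == "") path <- file.path("inst", "extdata", "site_presets.yaml")
  yaml::read_yaml(path)
}

#' Simulation configuration
#'
#' Assembles (and validates) the knobs of the synthetic cohort generator.
#' A `site_preset` (from `inst/extdata/site_presets.yaml`) provides the
#' defaults for severity mix, visit density and missingness; any explicitly
#' supplied argument overrides the preset.
#'
#' @param n_participants Cohort size.
#' @param visit_count Integer range `c(min, max)` of visits per participant
#'   (min >= 2).
#' @param interval_months Range of consecutive-visit gaps in months.
#' @param missingness Named rates in `[0, 1]` for blocks `cognitive`, `mri`,
#'   `diagnosis`.
#' @param site_preset Preset name (`"adni_like"`, `"macc_like"`,
#'   `"aibl_like"`) or `NULL`.
#' @param onset_mean,onset_sd Mean/SD (years) of the latent dementia onset age.
#' @param baseline_age_mean,baseline_age_sd Baseline age distribution (years).
#' @param apoe_shift_years Onset advance per APOE-e4 allele (years).
#' @param label_flip Probability that a visit's diagnosis label is flipped to
#'   a random other class.
#' @param noise_scale Multiplier on all biomarker noise SDs (0 = noise-free).
#' @param trajectories Named list of [trajectory_params()] per biomarker.
#' @param seed Integer seed.
#' @return An `l2c_sim_config` list.
#' @export
sim_config <- function(n_participants = 500,
                       visit_count = NULL,
                       interval_months = NULL,
                       missingness = NULL,
                       site_preset = "adni_like",
                       onset_mean = NULL,
                       onset_sd = NULL,
                       baseline_age_mean = 73,
                       baseline_age_sd = 7,
                       apoe_shift_years = 2.5,
                       label_flip = 0.05,
                       noise_scale = 1,
                       trajectories = default_trajectories(),
                       seed = 0) {
  preset <- list()
  if (!is.null(site_preset)) {
    presets <- site_presets()
    if (!site_preset %in% names(presets)) {
      stop("unknown site preset: ", site_preset)
    }
    preset <- presets[[site_preset]]
  }
  cfg <- list(
    n_participants = n_participants,
    visit_count = visit_count %||% unlist(preset$visit_count) %||% c(2L, 12L),
    interval_months = interval_months %||% unlist(preset$interval_months) %||% c(3, 12),
    missingness = missingness %||% unlist(preset$missingness) %||%
      c(cognitive = 0, mri = 0, diagnosis = 0),
    site_preset = site_preset,
    mmse_target = preset$baseline_mmse_target,
    mmse_tol = preset$baseline_mmse_tol %||% 1,
    onset_mean = onset_mean %||% preset$onset_mean %||% 76,
    onset_sd = onset_sd %||% preset$onset_sd %||% 8,
    baseline_age_mean = baseline_age_mean,
    baseline_age_sd = baseline_age_sd,
    apoe_shift_years = apoe_shift_years,
    label_flip = label_flip,
    noise_scale = noise_scale,
    trajectories = trajectories,
    seed = seed
  )
  with(cfg, {
    stopifnot(n_participants >= 1,
              length(visit_count) == 2, visit_count[1] >= 2,
              visit_count[1] <= visit_count[2],
              length(interval_months) == 2,
              interval_months[1] > 0,
              interval_months[1] <= interval_months[2],
              all(missingness >= 0), all(missingness <= 1),
              all(c("cognitive", "mri", "diagnosis") %in% names(missingness)),
              label_flip >= 0, label_flip <= 1, noise_scale >= 0)
  })
  if (cfg$visit_count[1] == cfg$visit_count[2] &&
      cfg$interval_months[1] == cfg$interval_months[2] &&
      cfg$interval_months[1] <= 0) {
    stop("degenerate visit schedule configuration")
  }
  structure(cfg, class = "l2c_sim_config")
}

# CDR staircase on the latent disease clock (years past onset).
severity_to_cdr <- function(s) {
  cut_points <- c(0, 6, 10, 14)
  vals <- c(0, 0.5, 1, 2, 3)
  vals[findInterval(s, cut_points) + 1L]
}

cdr_to_dx <- function(cdr) {
  ifelse(cdr >= 1, "DEM", ifelse(cdr >= 0.5, "MCI", "CN"))
}

#' Generate a synthetic longitudinal cohort
#'
#' Each participant receives a latent dementia onset age (advanced by
#' `apoe_shift_years` per APOE-e4 allele), an irregular visit schedule, and
#' biomarker values from logistic trajectories on the disease clock plus
#' Gaussian noise. CDR global is a monotone staircase of latent severity;
#' diagnosis follows CDR-consistent thresholds with independent label-flip
#' noise. Per-modality missingness is then applied (eligibility-preserving).
#' Fully reproducible from `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A cohort tibble (see [cohort_columns()]) with ICV-normalised ROI
#'   columns appended; the latent per-participant truth is in
#'   `attr(, "latent")`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "l2c_sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("S%04d", seq_len(n))

  sex <- sample(c("male", "female"), n, replace = TRUE)
  education <- round(pmin(pmax(stats::rnorm(n, 15, 3), 6), 22))
  marital <- sample(c("married", "not_married"), n, replace = TRUE, prob = c(0.7, 0.3))
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  baseline_age <- pmin(pmax(stats::rnorm(n, config$baseline_age_mean,
                                         config$baseline_age_sd), 55), 95)
  onset_age <- stats::rnorm(n, config$onset_mean, config$onset_sd) -
    config$apoe_shift_years * apoe4
  icv <- pmax(stats::rnorm(n, 1.5e6, 1.2e5), 1.1e6)
  n_visits <- sample(seq(config$visit_count[1], config$visit_count[2]),
                     n, replace = TRUE)

  traj <- config$trajectories
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n_visits[i]
    gaps <- stats::runif(m - 1, config$interval_months[1], config$interval_months[2])
    months <- c(0, cumsum(gaps))
    age <- baseline_age[i] + months / 12
    s <- age - onset_age[i]

    biomk <- lapply(traj, function(p) {
      logistic_value(s, p) +
        stats::rnorm(m, 0, p$noise_sd * config$noise_scale)
    })
    mmse <- round(pmin(pmax(biomk$mmse, 0), 30))
    s_obs <- s + stats::rnorm(m, 0, 1 * config$noise_scale)
    cdr <- severity_to_cdr(s_obs)
    dx <- cdr_to_dx(cdr)
    flip <- stats::runif(m) < config$label_flip
    if (any(flip)) {
      dx[flip] <- vapply(dx[flip], function(d)
        sample(setdiff(DX_LEVELS, d), 1), character(1))
    }
    rows[[i]] <- tibble::tibble(
      participant_id = ids[i], month = months, age = age,
      sex = sex[i], education_years = education[i], marital = marital[i],
      apoe4_count = apoe4[i],
      mmse = mmse, cdr_global = cdr, diagnosis = dx,
      hippocampus = pmax(biomk$hippocampus, 0),
      fusiform = pmax(biomk$fusiform, 0),
      midtemp = pmax(biomk$midtemp, 0),
      ventricle = pmax(biomk$ventricle, 0),
      wholebrain = pmax(biomk$wholebrain, 0),
      icv = icv[i]
    )
  }
  cohort <- dplyr::bind_rows(rows)
  cohort <- apply_missingness(cohort, config$missingness,
                              seed = config$seed + 1L)
  cohort <- normalize_by_icv(cohort)
  attr(cohort, "latent") <- tibble::tibble(
    participant_id = ids, baseline_age = baseline_age, onset_age = onset_age,
    apoe4_count = apoe4, n_visits = n_visits)
  cohort
}

#' Blank modality blocks at random (eligibility-preserving MCAR)
#'
#' Each visit's cognitive, MRI and diagnosis blocks are independently set to
#' missing with their configured rates. Two visits per participant are
#' protected: if all blocks of a protected visit were blanked, one randomly
#' chosen block is restored, so every participant keeps at least two visits
#' with a recurring feature and [filter_eligible()] passes by construction.
#'
#' @param cohort Cohort tibble.
#' @param rates Named rates for `cognitive`, `mri`, `diagnosis` in `[0, 1]`.
#' @param seed Integer seed.
#' @param severity_bias Stress-test hook for informative missingness: added
#'   to each block's blanking probability (clipped to `[0, 1]`) at visits
#'   with CDR global >= 1. Default 0 (MCAR).
#' @return The cohort with cells blanked.
#' @export
apply_missingness <- function(cohort, rates, seed = 1, severity_bias = 0) {
  stopifnot(all(c("cognitive", "mri", "diagnosis") %in% names(rates)),
            all(rates >= 0), all(rates <= 1))
  if (all(rates[c("cognitive", "mri", "diagnosis")] >= 1)) {
    stop("configured rates make eligibility impossible")
  }
  if (all(rates == 0) && severity_bias == 0) return(cohort)
  set.seed(seed)
  n <- nrow(cohort)
  blocks <- lapply(MODALITY_COLS, intersect, x = names(cohort))
  names(blocks) <- names(MODALITY_COLS)
  severe <- !is.na(cohort$cdr_global) & cohort$cdr_global >= 1
  # per-visit block blanking decisions
  blank <- sapply(names(blocks), function(b) {
    p <- pmin(pmax(rates[[b]] + severity_bias * severe, 0), 1)
    stats::runif(n) < p
  })
  original <- cohort

  # protect two random visits per participant
  prot <- unlist(lapply(split(seq_len(n), cohort$participant_id), function(idx) {
    if (length(idx) <= 2) idx else sample(idx, 2)
  }), use.names = FALSE)
  all_blanked <- rowSums(blank) == length(blocks)
  for (i in intersect(prot, which(all_blanked))) {
    keep <- sample(names(blocks), 1)
    blank[i, keep] <- FALSE
  }
  for (b in names(blocks)) {
    for (col in blocks[[b]]) cohort[[col]][blank[, b]] <- NA
  }
  # belt-and-braces: restore originals where a participant still fell short
  counts <- n_recurring_visits(cohort)
  short <- names(counts)[counts < 2]
  for (id in short) {
    idx <- which(cohort$participant_id == id)
    fix <- idx[seq_len(min(2, length(idx)))]
    cohort[fix, unlist(blocks)] <- original[fix, unlist(blocks)]
  }
  cohort
}
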