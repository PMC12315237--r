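# Shared column dictionaries and small helpers.

# Diagnosis severity order used everywhere: CN < MCI < DEM.
DX_LEVELS <- c("CN", "MCI", "DEM")

# Raw ROI volume columns (mm^3) and their ICV-normalised counterparts.
ROI_COLS <- c("hippocampus", "fusiform", "midtemp", "ventricle", "wholebrain")
ROI_ICV_COLS <- paste0(ROI_COLS, "_icv")

# The eight continuous modalities entering the L2C transformation.
CONTINUOUS_MODALITIES <- c("mmse", "cdr_global", ROI_ICV_COLS, "icv")

# Modality blocks as they appear in the visit table.
MODALITY_COLS <- list(
  cognitive = c("mmse", "cdr_global"),
  mri       = c(ROI_COLS, "icv", ROI_ICV_COLS),
  diagnosis = "diagnosis"
)

# Columns whose presence makes a visit count towards the >= 2 recurring-feature
# eligibility rule (cognitive scores, MRI volumes, clinical diagnosis).
RECURRING_COLS <- c("mmse", "cdr_global", ROI_COLS, "icv", "diagnosis")

# Baseline (time-invariant) covariates.
BASELINE_COLS <- c("sex", "education_years", "marital", "apoe4_count")

#' Column dictionary of the longitudinal cohort table
#'
#' The package works on a single tidy table with one row per participant-visit.
#' `cohort_columns()` returns the documented column names; extra columns in an
#' input table are ignored with a warning by [read_cohort()].
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("participant_id", "month", "age", BASELINE_COLS,
    "mmse", "cdr_global", "diagnosis", ROI_COLS, "icv")
}

dx_severity <- function(dx) {
  out <- match(dx, DX_LEVELS) - 1L
  if (anyNA(out[!is.na(dx)])) {
    bad <- unique(dx[!is.na(dx) & is.na(match(dx, DX_LEVELS))])
    stop("unknown diagnosis code(s): ", paste(bad, collapse = ", "))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
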