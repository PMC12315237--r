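# Site presets for the synthetic cohort generator. Each preset shifts the
# latent onset distribution (severity mix), visit density and per-modality
# missingness to mimic the contrasts seen between large ageing cohorts:
# an ADNI-like research cohort (mildly impaired on average, dense follow-up,
# substantial missingness), a MACC-like memory-clinic cohort (more severe,
# sparser follow-up, near-complete cognitive data) and an AIBL-like healthy
# ageing cohort. baseline_mmse_target is the preset's own expected baseline
# MMSE mean (computed from the generator at large n), used by marginal checks.
adni_like:
  onset_mean: 77.5
  onset_sd: 8
  visit_count: [2, 12]
  interval_months: [3, 12]
  missingness:
    cognitive: 0.30
    mri: 0.39
    diagnosis: 0.30
  baseline_mmse_target: 25.2
  baseline_mmse_tol: 1.0
macc_like:
  onset_mean: 70
  onset_sd: 7
  visit_count: [2, 6]
  interval_months: [6, 12]
  missingness:
    cognitive: 0.02
    mri: 0.53
    diagnosis: 0.01
  baseline_mmse_target: 20.4
  baseline_mmse_tol: 1.0
aibl_like:
  onset_mean: 80
  onset_sd: 8
  visit_count: [2, 4]
  interval_months: [9, 15]
  missingness:
    cognitive: 0.005
    mri: 0.23
    diagnosis: 0.005
  baseline_mmse_target: 26.3
  baseline_mmse_tol: 1.0
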