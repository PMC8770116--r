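- material: PVC
  density: 1.3
  dp_qspr:
    name: log_linear_log10_mw
    coefficients:
      intercept: -3.1
      log_mw_slope: -3.6
    mw_domain:
    - 50.0
    - 1000.0
  kms_qspr:
    name: kow_etoh_eq
    coefficients:
      intercept: 0.1
      kow_slope: 0.74
      etoh_slope: 1.0
  provenance: synthetic representative defaults (see package vignette)
- material: PP
  density: 0.9
  dp_qspr:
    name: log_linear_log10_mw
    coefficients:
      intercept: -3.0
      log_mw_slope: -3.6
    mw_domain:
    - 50.0
    - 1000.0
  kms_qspr:
    name: kow_etoh_eq
    coefficients:
      intercept: 0.0
      kow_slope: 0.7
      etoh_slope: 1.0
  provenance: synthetic representative defaults (see package vignette)
- material: EVA
  density: 0.93
  dp_qspr:
    name: log_linear_log10_mw
    coefficients:
      intercept: -2.3
      log_mw_slope: -2.7
    mw_domain:
    - 50.0
    - 1000.0
  kms_qspr:
    name: kow_etoh_eq
    coefficients:
      intercept: 0.0
      kow_slope: 0.66
      etoh_slope: 1.0
  provenance: synthetic representative defaults (see package vignette)
- material: silicone
  density: 1.1
  dp_qspr:
    name: log_linear_log10_mw
    coefficients:
      intercept: -2.1
      log_mw_slope: -2.4
    mw_domain:
    - 50.0
    - 1000.0
  kms_qspr:
    name: kow_etoh_eq
    coefficients:
      intercept: 0.3
      kow_slope: 0.72
      etoh_slope: 1.0
  provenance: synthetic representative defaults (see package vignette)
- material: wood
  density: 0.6
  dp_qspr:
    name: log_linear_log10_mw
    coefficients:
      intercept: -1.8
      log_mw_slope: -2.9
    mw_domain:
    - 50.0
    - 1000.0
  kms_qspr:
    name: kow_etoh_eq
    coefficients:
      intercept: -0.3
      kow_slope: 0.6
      etoh_slope: 1.0
  provenance: synthetic representative defaults (see package vignette)
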