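{
  "comment": "Hand-computed expectations for the 12-record toy fixture (exact fractions rendered as doubles). Scores fixed at 0.5 for all records; kernel counterfactual = mass-weighted comparison mean.",
  "total_mass": 14,
  "group_mass": 8,
  "polling_area_rural": {
    "mass": 5,
    "profile_mass": 8,
    "coverage": 0.625,
    "lambda": 0.375,
    "mu": 0.375,
    "psi_alpha_0_5": 0.375
  },
  "polling_area_rural_educ_none": {
    "mass": 3,
    "profile_mass": 5,
    "coverage": 0.375,
    "mu": 0.4
  },
  "impact_area_rural": {
    "att": 0.4,
    "se": 0.30550504633038933,
    "t": 1.3093073414159544,
    "pr_x": 0.5714285714285714,
    "pr_treated_given_x": 0.625,
    "ate_x": 0.25,
    "impact": 0.14285714285714285,
    "mu_impact": 0.375
  },
  "impact_area_urban": {
    "att": 0.33333333333333331,
    "pr_x": 0.42857142857142855,
    "pr_treated_given_x": 0.5,
    "impact": 0.071428571428571425
  },
  "area_universe": {
    "total_impact": 0.21428571428571427,
    "coverage_rural": 0.66666666666666663,
    "coverage_urban": 0.33333333333333331,
    "lambda_rural": 0.33333333333333331,
    "psi_rural_alpha_0_5": 0.35355339059327379,
    "psi_urban_alpha_0_5": 0.57735026918962573
  },
  "overlap_universe_rural_educnone": {
    "total_impact": 0.19642857142857142,
    "coverage_each": 0.72727272727272729
  }
}
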