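strata:
  label:
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  'n':
  - 680
  - 528
  - 445
  - 468
  - 352
  - 99
  age_min:
  - 18
  - 25
  - 35
  - 45
  - 55
  - 65
  age_max:
  - 24
  - 34
  - 44
  - 54
  - 64
  - 81
marginals:
  variable:
  - glucose
  - glucose
  - glucose
  - glucose
  - glucose
  - glucose
  - hba1c
  - hba1c
  - hba1c
  - hba1c
  - hba1c
  - hba1c
  - insulin
  - insulin
  - insulin
  - insulin
  - insulin
  - insulin
  - hdl
  - hdl
  - hdl
  - hdl
  - hdl
  - hdl
  - ldl
  - ldl
  - ldl
  - ldl
  - ldl
  - ldl
  - triglycerides
  - triglycerides
  - triglycerides
  - triglycerides
  - triglycerides
  - triglycerides
  - uric_acid
  - uric_acid
  - uric_acid
  - uric_acid
  - uric_acid
  - uric_acid
  - urea
  - urea
  - urea
  - urea
  - urea
  - urea
  - creatinine
  - creatinine
  - creatinine
  - creatinine
  - creatinine
  - creatinine
  - waist
  - waist
  - waist
  - waist
  - waist
  - waist
  - weight
  - weight
  - weight
  - weight
  - weight
  - weight
  - height
  - height
  - height
  - height
  - height
  - height
  - temperature
  - temperature
  - temperature
  - temperature
  - temperature
  - temperature
  - systolic
  - systolic
  - systolic
  - systolic
  - systolic
  - systolic
  - diastolic
  - diastolic
  - diastolic
  - diastolic
  - diastolic
  - diastolic
  stratum:
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  - <25
  - 25-34
  - 35-44
  - 45-54
  - 55-64
  - 65+
  mean:
  - 4.6
  - 4.7
  - 5.0
  - 5.0
  - 5.0
  - 6.0
  - 5.1
  - 5.1
  - 5.0
  - 6.0
  - 6.0
  - 6.0
  - 55.0
  - 54.0
  - 57.0
  - 60.0
  - 59.0
  - 59.0
  - 1.3
  - 1.2
  - 1.2
  - 1.2
  - 1.2
  - 1.3
  - 2.5
  - 3.0
  - 3.0
  - 3.2
  - 3.3
  - 3.2
  - 1.1
  - 1.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 323.0
  - 326.0
  - 319.0
  - 315.0
  - 331.0
  - 335.0
  - 4.0
  - 5.0
  - 4.0
  - 5.0
  - 5.0
  - 6.0
  - 70.0
  - 74.0
  - 70.0
  - 70.0
  - 74.0
  - 88.0
  - 82.0
  - 87.0
  - 91.0
  - 93.0
  - 93.0
  - 94.0
  - 63.0
  - 68.0
  - 72.0
  - 71.0
  - 70.0
  - 68.0
  - 162.0
  - 164.0
  - 162.0
  - 159.0
  - 160.0
  - 159.0
  - 37.2
  - 37.0
  - 37.0
  - 37.0
  - 36.8
  - 36.7
  - 109.0
  - 109.0
  - 113.0
  - 115.0
  - 121.0
  - 124.0
  - 71.0
  - 73.0
  - 76.0
  - 77.0
  - 79.0
  - 78.0
  sd:
  - 0.5
  - 0.7
  - 1.0
  - 2.0
  - 2.0
  - 2.0
  - 0.5
  - 0.6
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 36.0
  - 52.0
  - 42.0
  - 62.0
  - 40.0
  - 44.0
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.6
  - 1.0
  - 2.0
  - 0.8
  - 0.9
  - 0.8
  - 0.6
  - 1.0
  - 2.0
  - 1.0
  - 1.0
  - 1.0
  - 92.0
  - 90.0
  - 87.0
  - 82.0
  - 88.0
  - 85.0
  - 1.0
  - 2.0
  - 1.0
  - 1.0
  - 1.0
  - 2.0
  - 14.0
  - 45.0
  - 16.0
  - 17.0
  - 18.0
  - 78.0
  - 11.0
  - 12.0
  - 12.0
  - 12.0
  - 11.0
  - 12.0
  - 13.0
  - 15.0
  - 15.0
  - 14.0
  - 14.0
  - 13.0
  - 9.0
  - 9.0
  - 9.0
  - 9.0
  - 10.0
  - 10.0
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.6
  - 11.0
  - 12.0
  - 14.0
  - 14.0
  - 16.0
  - 19.0
  - 9.0
  - 9.0
  - 11.0
  - 10.0
  - 11.0
  - 11.0
  family:
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
  - normal
dependence:
  variables:
  - glucose
  - hba1c
  - insulin
  - hdl
  - ldl
  - triglycerides
  - uric_acid
  - urea
  - creatinine
  - waist
  - weight
  - height
  - temperature
  - systolic
  - diastolic
  values:
  - 1.0
  - 0.6
  - 0.45
  - 0.0
  - 0.0
  - 0.3
  - 0.0
  - 0.0
  - 0.0
  - 0.25
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.6
  - 1.0
  - 0.35
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.45
  - 0.35
  - 1.0
  - -0.25
  - 0.0
  - 0.35
  - 0.0
  - 0.0
  - 0.0
  - 0.35
  - 0.35
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.25
  - 1.0
  - 0.05
  - -0.4
  - -0.2
  - 0.0
  - 0.0
  - -0.2
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.05
  - 1.0
  - 0.3
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.3
  - 0.0
  - 0.35
  - -0.4
  - 0.3
  - 1.0
  - 0.3
  - 0.0
  - 0.0
  - 0.3
  - 0.3
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.2
  - 0.0
  - 0.3
  - 1.0
  - 0.3
  - 0.35
  - 0.3
  - 0.35
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.3
  - 1.0
  - 0.5
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.35
  - 0.5
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.25
  - 0.0
  - 0.35
  - -0.2
  - 0.0
  - 0.3
  - 0.3
  - 0.0
  - 0.0
  - 1.0
  - 0.7
  - 0.1
  - 0.0
  - 0.25
  - 0.2
  - 0.0
  - 0.0
  - 0.35
  - 0.0
  - 0.0
  - 0.3
  - 0.35
  - 0.0
  - 0.0
  - 0.7
  - 1.0
  - 0.45
  - 0.0
  - 0.25
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.1
  - 0.45
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.25
  - 0.25
  - 0.0
  - 0.0
  - 1.0
  - 0.7
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.2
  - 0.0
  - 0.0
  - 0.0
  - 0.7
  - 1.0
female_fraction: 0.65
seed: 1
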