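- state: hyperglycemia
  inputs: glucose
  direction: above
  cutoff:
  - 5.55
- state: high_hba1c
  inputs: hba1c
  direction: above
  cutoff:
  - 6.5
- state: insulin_resistance
  inputs:
  - glucose
  - insulin
  direction: above
  cutoff:
    M: 1.7
    F: 1.8
  derived: homa_ir
- state: low_hdl
  inputs: hdl
  direction: below
  cutoff:
    M: 1.03
    F: 1.3
- state: high_ldl
  inputs: ldl
  direction: above
  cutoff:
  - 3.0
- state: hypertriglyceridemia
  inputs: triglycerides
  direction: above
  cutoff:
  - 1.7
- state: hyperuricemia
  inputs: uric_acid
  direction: above
  cutoff:
  - 405.0
- state: azotemia
  inputs: urea
  direction: above
  cutoff:
  - 7.5
- state: low_egfr
  inputs: creatinine
  direction: below
  cutoff:
  - 90.0
  derived: egfr
- state: overweight
  inputs: waist
  direction: above
  cutoff:
    M: 90.0
    F: 80.0
- state: high_temperature
  inputs: temperature
  direction: above
  cutoff:
  - 37.0
- state: high_blood_pressure
  inputs:
  - systolic
  - diastolic
  direction: above
  cutoff:
    systolic: 120.0
    diastolic: 80.0
  derived: bp_either
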