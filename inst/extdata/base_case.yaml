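clinical:
  start_age: 61.0
  cohort_size: 197.0
  annual_syncope_rate: 0.6
  diagnosis_prob_ilr: 0.628
  diagnosis_prob_cdp: 0.125
  battery_life_years: 3.0
  mortality_hazard_ratio: 1.32
  injury_prob_per_event: 0.522
  severe_injury_fraction: 0.1616
  horizon_years: 30.0
  cycle_length_years: 0.25
costs:
  device_acquisition: 2000.0
  implantation: 127.8
  explantation: 127.8
  followup_visit: 31.0
  followup_visits_per_year: 2.0
  minor_trauma_tariff: 2684.83
  major_trauma_tariff: 6058.25
  trauma_cost_per_event: 1687.57
  annual_discount_rate: 0.05
scenarios:
- name: Sousa Pedro
  printed_total: 164.32
  items:
  - test: Standard electrocardiogram
    unit_price: 6.5
    fraction: 1.0
  - test: Echocardiography
    unit_price: 53.2
    fraction: 0.722
  - test: Overload echocardiography
    unit_price: 85.3
    fraction: 0.016
  - test: In-hospital ECG monitoring
    unit_price: 124.7
    fraction: 0.612
  - test: Exercise testing
    unit_price: 32.1
    fraction: 0.196
  - test: MRI or CT scan
    unit_price: 97.45
    fraction: 0.016
  - test: Electroencephalography
    unit_price: 58.8
    fraction: 0.012
  - test: Carotid sinus massage
    unit_price: 6.5
    fraction: 0.029
  - test: Carotid echo-doppler
    unit_price: 23.17
    fraction: 0.127
  - test: TILT test
    unit_price: 124.1
    fraction: 0.159
  - test: External loop recording
    unit_price: 47.3
    fraction: 0.118
  - test: Hypertension map
    unit_price: 59.2
    fraction: 0.069
- name: Edvardsson
  printed_total: 1112.02
  items:
  - test: Standard electrocardiogram
    unit_price: 6.5
    fraction: 0.98
  - test: Echocardiography
    unit_price: 53.2
    fraction: 0.86
  - test: Basic laboratory tests (with enzymes)
    unit_price: 65.87
    fraction: 0.86
  - test: Ambulatory ECG monitoring
    unit_price: 43.7
    fraction: 0.67
  - test: In-hospital ECG monitoring
    unit_price: 124.7
    fraction: 0.55
  - test: Exercise testing
    unit_price: 32.1
    fraction: 0.52
  - test: MRI or CT scan
    unit_price: 97.45
    fraction: 0.47
  - test: Electroencephalography
    unit_price: 58.8
    fraction: 0.39
  - test: Carotid sinus massage
    unit_price: 6.5
    fraction: 0.36
  - test: TILT test
    unit_price: 124.1
    fraction: 0.35
  - test: Electrophysiology testing
    unit_price: 2488.72
    fraction: 0.25
  - test: Coronary angiography
    unit_price: 531.44
    fraction: 0.23
  - test: External loop recording
    unit_price: 47.3
    fraction: 0.12
  - test: Orthostatic blood pressure movements
    unit_price: 4.0
    fraction: 0.48
  - test: Neurological or psychiatric evaluation
    unit_price: 30.9
    fraction: 0.47
- name: Baron-Esquivias
  printed_total: 88.51
  items:
  - test: Standard electrocardiogram
    unit_price: 6.5
    fraction: 0.956
  - test: Echocardiography
    unit_price: 53.2
    fraction: 0.021
  - test: Basic laboratory tests (without enzymes)
    unit_price: 53.87
    fraction: 0.702
  - test: Enzymes
    unit_price: 34.4
    fraction: 0.302
  - test: In-hospital ECG monitoring
    unit_price: 124.7
    fraction: 0.171
  - test: Brain CT scan
    unit_price: 67.0
    fraction: 0.09
  - test: Thorax CT scan
    unit_price: 74.7
    fraction: 0.011
  - test: Chest X-ray
    unit_price: 9.0
    fraction: 0.519
  - test: Carotid sinus massage
    unit_price: 6.5
    fraction: 0.005
  - test: Orthostatic blood pressure movements
    unit_price: 4.0
    fraction: 0.046
- name: Brignole
  printed_total: 173.31
  items:
  - test: Standard electrocardiogram
    unit_price: 6.5
    fraction: 1.0
  - test: Echocardiography
    unit_price: 53.2
    fraction: 0.16
  - test: Abdominal echography
    unit_price: 20.12
    fraction: 0.02
  - test: Basic laboratory tests (with enzymes)
    unit_price: 65.87
    fraction: 0.35
  - test: In-hospital ECG monitoring
    unit_price: 124.7
    fraction: 0.11
  - test: Exercise testing
    unit_price: 32.1
    fraction: 0.03
  - test: MRI or CT scan
    unit_price: 97.45
    fraction: 0.15
  - test: Chest X-ray
    unit_price: 9.0
    fraction: 0.12
  - test: Electroencephalography
    unit_price: 58.8
    fraction: 0.06
  - test: Carotid sinus massage
    unit_price: 6.5
    fraction: 0.15
  - test: Carotid echo-doppler
    unit_price: 23.17
    fraction: 0.04
  - test: TILT test
    unit_price: 124.1
    fraction: 0.13
  - test: Electrophysiology testing
    unit_price: 2488.72
    fraction: 0.03
  - test: Coronary angiography
    unit_price: 531.44
    fraction: 0.02
- name: Farwell
  printed_total: 72.41
  items:
  - test: Echocardiography
    unit_price: 53.2
    fraction: 0.1531
  - test: Ambulatory ECG monitoring
    unit_price: 43.7
    fraction: 0.1122
  - test: External loop recorder (ELR)
    unit_price: 47.3
    fraction: 0.2857
  - test: MRI
    unit_price: 127.9
    fraction: 0.0102
  - test: Brain CT scan
    unit_price: 67.0
    fraction: 0.0816
  - test: Electroencephalography
    unit_price: 58.8
    fraction: 0.0204
  - test: Carotid echo-doppler
    unit_price: 23.17
    fraction: 0.051
  - test: Electrophysiology testing
    unit_price: 2488.72
    fraction: 0.0102
base_scenario: Sousa Pedro
life_table_path: life_table_synthetic.tsv
workup_cost_per_event: 164.32
conventions:
  rate_conversion: linear
  event_order: simultaneous
  discount_convention: per-cycle
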