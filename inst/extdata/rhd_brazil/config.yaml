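states:
- id: A
  label: No RHD
- id: B
  label: Undiagnosed Asymptomatic Borderline RHD
- id: C
  label: Untreated Asymptomatic Definite RHD
- id: D
  label: Untreated Mild Clinical RHD
- id: E
  label: Untreated Severe Clinical RHD
- id: F
  label: Diagnosed Borderline RHD
- id: G
  label: Treated Asymptomatic Definite RHD
- id: H
  label: Treated Mild Clinical RHD
- id: I
  label: Treated Severe Clinical RHD
- id: RG
  label: Resolved RHD (from treated asymptomatic definite)
- id: RH
  label: Resolved RHD (from treated mild clinical)
- id: RI
  label: Resolved RHD (from treated severe clinical)
- id: K
  label: Post Surgery
- id: X
  label: Surgery
- id: Z
  label: Death
death_state: Z
tunnel_states:
- X
initial_distribution:
  A: 0.95799999999999996
  B: 0.0315
  C: 0.0105
cohort_size: 1000
n_cycles: 30
start_age: 11.0
discount_rate: 0.03
threshold: 25949.84999999999854481
screening:
  cost_per_scan: 6.59999999999999964
  sensitivity_borderline: 0.65000000000000002
  sensitivity_definite: 0.90000000000000002
  specificity: 0.94999999999999996
  false_positive_followup_cost: 30.0
  screened_fraction: 1.0
  owsa:
    sensitivity_borderline:
    - 0.5
    - 0.80000000000000004
    sensitivity_definite:
    - 0.80000000000000004
    - 1.0
    specificity:
    - 0.90000000000000002
    - 0.98999999999999999
prophylaxis:
  effect_definite: 0.5
  effect_mild: 0.5
  definite_from: G
  definite_to:
  - H
  - X
  mild_from: H
  mild_to: I
roles:
  disease_free:
  - A
  undiagnosed_borderline:
  - B
  diagnosed_borderline:
  - F
  undiagnosed_definite:
  - C
  treated_definite:
  - G
  borderline_states:
  - B
  - F
  definite_states:
  - C
  - G
shared_cost_variance: 1528074.23940900014713407
files:
  transitions: transitions_synthetic.csv
  economics: economics.csv
  lifetable: lifetable_synthetic.csv
  allowed_edges: allowed_edges.csv
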