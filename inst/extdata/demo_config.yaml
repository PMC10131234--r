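# Demonstration pipeline configuration: a small synthetic study with a
# pandemic-style disruption injected into every code beginning "Aa"
# (an 85% April drop with linear recovery to baseline by December) and a
# sustained 40% drop for codes beginning "Bb".
seed: 1
synthetic:
  n_practices: 50
  n_codes: 20
  attrition_fraction_start: 0.07
  profiles:
    - prefixes: ["Aa"]
      disruption_month: "2020-04"
      drop_fraction: 0.85
      recovery_shape: linear
      recovery_months: 8
      terminal_level: 1.0
    - prefixes: ["Bb"]
      disruption_month: "2020-04"
      drop_fraction: 0.6
      recovery_shape: linear
      recovery_months: 8
      terminal_level: 0.6
discovery:
  threshold: 1000
  threshold_year: 2020
  topics:
    - topic: cardiovascular
      prefixes: ["Aa"]
      keywords: ["cardiovascular"]
    - topic: medication
      keywords: ["medication", "review"]
measures:
  disruption_month: "2020-04"
  final_month: "2020-12"
  key_months: ["2020-02", "2020-04", "2020-12"]
  window_months: 3
report:
  charts: true
  chart_subjects: 4
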