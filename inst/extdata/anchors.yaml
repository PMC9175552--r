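crossings:
- group: gt60
  target: 0.0
  dose: 1.1
- group: gt60
  target: 2.0
  dose: 4.2
- group: le60
  target: 0.0
  dose: 1.8
- group: le60
  target: 2.0
  dose: 5.5
- group: oe
  target: 0.0
  dose: 5.5
inequality:
  group: oe
  target: 2.0
  dose_min: 8.0
tails:
  low:
    policy:
      le60: 1.5
      gt60: 1.0
      oe: 2.0
    p_below_m2: 0.1
    p_above_2: 0.01
  high:
    policy:
      le60: 2.0
      gt60: 1.5
      oe: 4.0
    p_below_m2: 0.05
    p_above_2: 0.05
somatropin:
  soma_dose: 2.364
  trop_dose: 0.289
  missed3_deficit: 0.4
  match_tol: 0.02
  deficit_tol: 0.05
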