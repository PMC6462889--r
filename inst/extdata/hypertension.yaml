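# Two blood-pressure medications, 2 blocks x 30-day periods, daily cuff
# readings. Treatment 1 is stronger but slower to wash in.
design:
  n_blocks: 2
  n_treatments: 2
  period_length_days: 30
  block_orders:
    - [2, 1]
    - [2, 1]
  sampling:
    mode: regular
    interval_days: 1
  dt_days: 0.1
treatments:
  - {effect: -40.0, wash_in_tau: 6.0, wash_out_gamma: 3.0}
  - {effect: -30.0, wash_in_tau: 2.0, wash_out_gamma: 10.0}
outcome:
  baseline_init: 160.0
  sensitivity: 0.5
  sigma_b: 0.9
  sigma_p: 1.0
  sigma_o: 4.0
  outcome_type: numeric
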