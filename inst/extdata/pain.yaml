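# NSAID (treatment 1) vs paracetamol (treatment 2), daily 0-6 diary
# score, 5 blocks of two 14-day periods; analyze the last week of each
# period. Paracetamol is the reference state (baseline = its true score).
design:
  n_blocks: 5
  n_treatments: 2
  period_length_days: 14
  block_orders: random
  order_seed: 1
  sampling:
    mode: regular
    interval_days: 1
  dt_days: 0.1
treatments:
  - {effect: -2.0, wash_in_tau: 1.0, wash_out_gamma: 3.5}
  - {effect: 0.0, wash_in_tau: 1.0, wash_out_gamma: 3.5}
outcome:
  baseline_init: 4.0
  sensitivity: 1.0
  sigma_b: 0.0
  sigma_p: 0.5
  sigma_o: 1.0
  outcome_type: score
  outcome_max: 6
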