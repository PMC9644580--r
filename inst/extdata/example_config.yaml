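# Example analysis configuration: small synthetic cohort, full pipeline.
output_dir: cadcea_output
seed: 42
n_draws: 200
patients_per_year: 6000
base_strategy: current_practice
cohort:
  n_patients: 2000
  n_cycles: 20
engine:
  cycle_length: 0.5
  n_cycles: 20
  cohort_size: 10000
  annual_discount_rate: 0.03
  half_cycle_correction: true
  mortality_increment: 0.01
  mortality_block: 10
  wtp_threshold: 80000
strategies:
  current_practice: {OMT: 0.819, PCI: 0.135, CABG: 0.046}
  all_cabg: {CABG: 1.0}
  all_omt: {OMT: 1.0}
  all_pci: {PCI: 1.0}
  recommended: {OMT: 0.86, CABG: 0.14}
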