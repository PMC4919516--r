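# Demonstration pipeline configuration: a small synthetic session with two
# selective subpopulations (urine- vs faeces-preferring) plus non-responders.
seed: 101
n_cells: 24
baseline_hz: 2
trials_per_stimulus: 5
stimulus_duration_s: 4
inter_onset_s: 20
jitter_sd: 0.2
panel:
  control: ringers
  stimuli:
    - id: ringers
      label: "Ringer's solution"
      tag: control
    - id: urine
      label: "female urine 1:100"
      tag: urine
    - id: faeces
      label: "female faecal extract 1:300"
      tag: faeces
effects:              # cells 1-10 urine-tuned, 11-20 faeces-tuned, 21-24 silent
  - cells: [1, 10]
    stimulus: urine
    delta_hz: 8
  - cells: [11, 20]
    stimulus: faeces
    delta_hz: 8
clustering:
  n_runs: 300
  k_range: [2, 3, 4, 5, 6, 7, 8]
shuffle:
  stim_a: urine
  stim_b: faeces
  n_model: 2000
  mode: trial_sets
categories:
  urine: [urine]
  faeces: [faeces]
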