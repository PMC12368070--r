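seed: 1
replicates: 2
genome:
  n_genes: 20
  length_min: 5000
  length_max: 40000
  spacing: 10000
analysis:
  bootstrap_iters: 200
  tss_window_bp: 5000
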