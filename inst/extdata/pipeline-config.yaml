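# Default end-to-end pipeline configuration (desk scale).
targetome:
  n_families: 6        # seed families in the pool
  n_genes: 12          # gene panel ("channelome") size
  utr_length: 300      # nt per 3' UTR
  sites_per_gene: [1, 3]
  gc_content: 0.45
expression:
  n_entities: 60       # miRNAs per abundance table
  n_top: 20            # top-N expression gate
  n_expressed_in_both: 20
enrichment:
  n_terms: 6
  term_size: 6
de:
  n_genes: 1000
  n_targets: 100
  target_shift: -0.5   # log2 units; negative = repression by the mimic
  sd_log2fc: 0.3
apd:
  n_beats: 10
  beat_interval: 640   # ms; spontaneous beating faster than 1 Hz
  upstroke_duration: 10
  plateau_duration: 130
  repolarization_duration: 250
  noise_sd: 0.02
  drift_per_s: -0.01   # photobleaching
rp:
  true_rp: 400         # ms
  step_ms: 50
  noise_sd: 0.05
reporter:
  n_cells: 300
  repression_factor: 0.7
  cv: 0.1
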