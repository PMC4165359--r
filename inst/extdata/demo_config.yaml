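# Demonstration configuration for the full synthetic pipeline.
# Small genome so the end-to-end run finishes in well under a minute.
out_dir: fungimeth_demo
window_size: 25000
cnv_threshold: 0.3
min_coverage: 4
rpkm_threshold: 1
delta_cut: 0.05
sim:
  genome_length: 300000
  n_scaffolds: 2
  te_fraction: 0.58
  te_island_size: 15000
  gene_block_size: 10000
  coverage: 8
  read_length: 50
  conversion_failure: 0.005
  sequencing_error: 0.001
  seed: 11
cnv_plant:
  scaffold: [scaffold_01]
  start: [25000]
  end: [75000]
  fold: [2]
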