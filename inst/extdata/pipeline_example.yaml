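# Small fully synthetic end-to-end run; see ?run_pipeline.
seed: 1
outdir: redchip_example_out
bridge:
  bridge_seq: GTTGGAGTTCGGTGTGAGGC
  max_mismatches: 1
  dna_tag_min: 18
  dna_tag_max: 22
  rna_min_len: 14
  gggg_trim: true
simulate:
  seed: 1
  n_chroms: 2
  chrom_length: 200000
  n_genes: 40
  gene_length_range: [500, 2000]
  state_block_bp: 25000
  n_peaks: 10
  n_contacts_per_fraction: 1000
  cis_decay_scale: 5000
analysis:
  mode: cis
  window_bp: 1000000
  threshold: 1.3
  min_count: 5
  flank_bp: 10000
  n_bins: 41
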