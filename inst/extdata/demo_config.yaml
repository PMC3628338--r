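# Demo pipeline configuration. Relative paths are resolved against the
# directory containing this file.
seed: 42
output_dir: famdiv_demo_out
stages: [simulate, synteny, fst, enrich, density, ld, cnv]
thresholds:
  tandem_gap: 500000
  min_markers: 2
  max_gap: 2000000
  ld_r2: 0.8
  brackets: [15, 10, 5, 1]
  cnv_min_len: 500
  freq_threshold: 0.01
  locus: {chrom: chr19, start: 47600000, end: 48500000}
simulate:
  n_populations: 3
  n_per_pop: 30
  n_snps: 400
  target_fst: 0.10
  n_genes: 40
  family_fraction: 0.15
  ld_snps: 12
  landscape:
    n_markers: 4
    n_tandem_arrays: 1
    n_wgd_blocks: 1
    n_singleton_blocks: 1
    tandem_size: 3
  cnv:
    n_individuals: 60
    population: CEU
paths:
  cnv_catalog: psg_cnv_catalog_synthetic.tsv
  baseline: psg_baseline.tsv
family: FAM
conserved: BG
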