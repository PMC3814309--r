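# Example run configuration: 15 J/m2 on the default synthetic genome.
# Any omitted field keeps its documented default.
seed: 7
n_cells: 50
genome:
  source: default
  seed: 1
sim:
  dose: 15
  noise_sd: 0.1
caller:
  min_run: 2
classifier:
  gap_kb: 15
  tol_snps: 1
stats:
  n_perm: 1000
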