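# Demo pipeline configuration: the default synthetic cohort (10 sexual
# diploid, 12 triploid + 4 tetraploid asexual lineages at 25x depth).
sim:
  seed: 42
  n_sexual: 10
  n_asexual_triploid: 12
  n_asexual_tetraploid: 4
  base_depth: 25
  dispersion: 10
  sexual_cn_range: [10, 30]
  asexual_cn_range: [100, 300]
  n_exons: 12
tolerance: 0.10
outlier_factor: 2
evalue_cutoff: 1.0e-50
gee_response: "5.8S"
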