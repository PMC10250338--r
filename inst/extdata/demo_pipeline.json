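{
  "seed": 42,
  "simulate": {
    "enabled": true,
    "n_reads": 300,
    "sub_rate": 0.02,
    "indel_rate": 0.01,
    "fraction_homo": 0.02,
    "fraction_hetero": 0.02
  },
  "classify": {
    "min_identity_collect": 0.8,
    "min_identity_strict": 0.9,
    "min_cds_fraction": 0.8
  },
  "annotate": {
    "min_share": 2,
    "min_identity": 0.9,
    "link_identity": 0.8
  }
}
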