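{
  "stage": "simulate",
  "package_version": "0.1.0",
  "r_version": "4.3.3",
  "timestamp": "2026-10-01T01:04:35+0000",
  "config": {
    "out_dir": "inst/extdata/example",
    "seed": 424,
    "n_neoblasts": 6,
    "L_n": 120,
    "L_m": 90,
    "coding_n": "1-60",
    "coding_m": "1-90",
    "mu_n": 0.0003,
    "mu_m": 0.0003,
    "n_pop": 8,
    "n_populations": 2,
    "generations": 40,
    "n_individuals": 2,
    "n_clones": 10
  }
}
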