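{
  "scenario": {
    "n_taxa": 30,
    "n_treatments": 2,
    "n_replicates": 3,
    "n_timepoints": 6,
    "reads_per_sample": 1000,
    "community_size": 2000,
    "regime": "variable_selection",
    "selection_sd": {},
    "trait_bm_rate": 1,
    "environment_values": {},
    "pool_overlap": 1,
    "mixing_rate": 0.5,
    "pool_sdlog": 2,
    "guild_size": 30,
    "seed": 42
  },
  "expected_process": {
    "between_cs": "variable_selection"
  },
  "planted_couplings": {},
  "note": "synthetic fixture; generator parameters are artifact choices"
}
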