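{
  "seed": 20,
  "genome_length": 30000,
  "gc_fraction": 0.5,
  "plants": [
    {"motif": "GATC", "focal": 2, "count": 80, "mod_multiplier": 8.57}
  ],
  "motifs": [
    {"motif": "GATC", "focal": 2},
    {"motif": "ATGCAT", "focal": 5}
  ],
  "kinetics": {"coverage_per_strand": 30, "log_sigma": 0.4},
  "min_valid": 25,
  "pct": 1.0,
  "flank": 10,
  "window": 41,
  "alpha": 0.01,
  "fold_call": 2,
  "replicate_concordance": true,
  "write_reads": false,
  "config_version": 1
}
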