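{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mosqconv analysis report",
  "type": "object",
  "required": ["seed", "timings"],
  "properties": {
    "seed": {"type": "integer"},
    "timings": {"type": "object"},
    "config": {"type": "object"},
    "coverage": {"type": "object", "required": ["totals"]},
    "asr": {"type": "object", "required": ["best_kind", "root_probs"]},
    "mapping": {"type": "object", "required": ["n_maps", "root_probs"]},
    "mca": {"type": "object", "required": ["eigenvalues", "percent"]},
    "signal": {"type": "object"},
    "manova": {"type": "object"},
    "wheatsheaf": {"type": "object"},
    "models": {"type": "object", "required": ["table"]},
    "envelope": {"type": "object", "required": ["pass_fraction"]}
  }
}
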