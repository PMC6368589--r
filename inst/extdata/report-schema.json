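{
  "title": "spinecorr report summary",
  "type": "object",
  "required": [
    "seed",
    "n_records",
    "n_by_condition",
    "bands",
    "group_stats",
    "perforation",
    "log"
  ],
  "properties": {
    "seed": { "type": "integer" },
    "n_records": { "type": "integer" },
    "n_by_condition": { "type": "object" },
    "density": { "type": ["object", "null"] },
    "bands": {
      "type": "object",
      "description": "per parameter pair: bands_<condition> summaries (v_lo, v_hi, n_spines) and the 2x2 chi-square on decoupled counts"
    },
    "group_stats": { "type": "object" },
    "perforation": { "type": "object" },
    "log": { "type": "array", "items": { "type": "string" } }
  }
}
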