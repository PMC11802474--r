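{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "seqscope QC report",
  "type": "object",
  "required": ["metadata", "summary", "positions", "adapters",
               "insert_sizes", "duplication", "overrepresented",
               "per_tile", "ont", "warnings"],
  "properties": {
    "metadata": {
      "type": "object",
      "required": ["tool", "version", "schema_version", "inputs", "paired",
                   "config"],
      "properties": {
        "tool": {"const": "seqscope"},
        "schema_version": {"type": "string"},
        "inputs": {"type": ["array", "string"]},
        "paired": {"type": "boolean"},
        "config": {"type": "object"}
      }
    },
    "summary": {
      "type": "object",
      "required": ["n_reads", "total_bases", "length_histogram",
                   "gc_histogram", "mean_quality_expected_error",
                   "mean_quality_arithmetic"],
      "properties": {
        "n_reads": {"type": "integer", "minimum": 0},
        "total_bases": {"type": "number", "minimum": 0}
      }
    },
    "positions": {"type": "array"},
    "adapters": {
      "type": "object",
      "required": ["total_reads", "probes"]
    },
    "insert_sizes": {"type": "object"},
    "duplication": {
      "type": "object",
      "required": ["dedup_fraction", "total_reads", "depth", "exact",
                   "multiplicity"]
    },
    "overrepresented": {
      "type": "object",
      "required": ["sampled_reads", "table_saturated", "table"]
    },
    "per_tile": {"type": "object"},
    "ont": {"type": "object"},
    "warnings": {"type": "array"}
  }
}
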