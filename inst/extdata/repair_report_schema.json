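{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "oligorepair repair report",
  "type": "object",
  "required": ["file", "entries"],
  "properties": {
    "file": { "type": "string" },
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["cluster_id", "original_centroid", "chosen", "edits", "n_changes", "category"],
        "properties": {
          "cluster_id": { "type": "string" },
          "original_centroid": { "type": "string", "pattern": "^[ACGTN]*$" },
          "chosen": { "type": ["string", "null"], "pattern": "^[ACGTN]*$" },
          "edits": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["op", "pos"],
              "properties": {
                "op": { "enum": ["substitution", "deletion", "insertion"] },
                "pos": { "type": "integer", "minimum": 0 },
                "from": { "type": "string", "pattern": "^[ACGTN]$" },
                "to": { "type": "string", "pattern": "^[ACGTN]$" }
              }
            }
          },
          "n_changes": { "type": "integer", "minimum": 0 },
          "category": { "enum": ["correct", "substituted", "repaired", "unrecoverable"] }
        }
      }
    }
  }
}
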