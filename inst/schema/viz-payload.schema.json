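{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "percolink-viz-payload",
  "title": "percolink visualization payload",
  "description": "Everything a front-end needs to display an association-network percolation trajectory: annotated nodes, the deterministically sorted edge list, per-step clustering statistics, the smallest-largest optimum and (optionally) one subgraph snapshot.",
  "type": "object",
  "required": ["schema_version", "rank_by", "nodes", "edges", "steps"],
  "properties": {
    "schema_version": { "const": "1.0" },
    "rank_by": { "enum": ["value", "abs_value"] },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "label": { "type": "string" },
          "group": { "type": ["string", "null"] },
          "color": { "type": ["string", "null"] }
        }
      }
    },
    "edges": {
      "type": "array",
      "description": "Sorted descending by ordering key, ties broken lexicographically by (source, target).",
      "items": {
        "type": "object",
        "required": ["source", "target", "strength"],
        "properties": {
          "source": { "type": "string" },
          "target": { "type": "string" },
          "strength": { "type": "number" }
        }
      }
    },
    "steps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["step_index", "threshold", "n_edges", "n_subgraphs",
                     "n_triples", "avg_size", "avg_density", "max_size",
                     "n_clustered", "rel_max_size"],
        "properties": {
          "step_index": { "type": "integer", "minimum": 1 },
          "threshold": { "type": "number" },
          "n_edges": { "type": "integer", "minimum": 1 },
          "n_subgraphs": { "type": "integer", "minimum": 1 },
          "n_triples": { "type": "integer", "minimum": 0 },
          "avg_size": { "type": "number", "minimum": 2 },
          "avg_density": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
          "max_size": { "type": "integer", "minimum": 2 },
          "n_clustered": { "type": "integer", "minimum": 2 },
          "rel_max_size": { "type": "number", "exclusiveMinimum": 0 }
        }
      }
    },
    "optimal": {
      "type": ["object", "null"],
      "required": ["threshold", "step_index", "rel_max_size_at_min", "eligible_steps"],
      "properties": {
        "threshold": { "type": "number" },
        "step_index": { "type": "integer", "minimum": 1 },
        "rel_max_size_at_min": { "type": "number" },
        "eligible_steps": { "type": "integer", "minimum": 1 }
      }
    },
    "snapshot": {
      "type": "object",
      "required": ["threshold", "subgraphs", "members", "unclustered"],
      "properties": {
        "threshold": { "type": "number" },
        "subgraphs": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["subgraph", "size", "n_edges", "density", "mean_strength"],
            "properties": {
              "subgraph": { "type": "integer", "minimum": 1 },
              "size": { "type": "integer", "minimum": 2 },
              "n_edges": { "type": "integer", "minimum": 1 },
              "density": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
              "mean_strength": { "type": "number" }
            }
          }
        },
        "members": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["id", "subgraph"],
            "properties": {
              "id": { "type": "string" },
              "subgraph": { "type": "integer", "minimum": 1 }
            }
          }
        },
        "unclustered": { "type": "array", "items": { "type": "string" } }
      }
    }
  }
}
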