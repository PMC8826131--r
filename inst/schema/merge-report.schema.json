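{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ctstitch vertical-merge report",
  "type": "object",
  "required": ["parameters", "acquisitions", "merges", "output"],
  "properties": {
    "parameters": {
      "type": "object",
      "required": ["window", "sigma_px", "allow_zero_overlap"],
      "properties": {
        "window": {"type": "integer", "minimum": 1},
        "sigma_px": {"type": "number", "exclusiveMinimum": 0},
        "allow_zero_overlap": {"type": "boolean"},
        "scaling": {
          "type": ["object", "null"],
          "required": ["lo", "hi"],
          "properties": {
            "lo": {"type": "number"},
            "hi": {"type": "number"}
          }
        }
      }
    },
    "acquisitions": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["label", "motor_z_mm", "slice_spacing_mm", "n_slices",
                     "orientation"],
        "properties": {
          "label": {"type": "string"},
          "motor_z_mm": {"type": "number"},
          "slice_spacing_mm": {"type": "number", "exclusiveMinimum": 0},
          "n_slices": {"type": "integer", "minimum": 1},
          "orientation": {"enum": ["down", "up"]}
        }
      }
    },
    "merges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["bottom", "top", "coarse_overlap_slices",
                     "refined_overlap_slices"],
        "properties": {
          "bottom": {"type": "string"},
          "top": {"type": "string"},
          "coarse_overlap_slices": {"type": "integer", "minimum": 0},
          "refined_overlap_slices": {"type": "integer", "minimum": 0},
          "reference_index_top": {"type": "integer", "minimum": 0},
          "best_target_index_bottom": {"type": "integer", "minimum": 0},
          "min_score": {"type": "number", "minimum": 0},
          "n_tied": {"type": "integer", "minimum": 1},
          "at_window_edge": {"type": "boolean"},
          "score_table": {
            "type": "object",
            "required": ["candidate", "score"],
            "properties": {
              "candidate": {"type": "array", "items": {"type": "integer"}},
              "score": {"type": "array", "items": {"type": "number"}}
            }
          },
          "warnings": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "output": {
      "type": "object",
      "required": ["n_slices", "dtype", "voxel_size_um"],
      "properties": {
        "n_slices": {"type": "integer", "minimum": 1},
        "dtype": {"enum": ["uint16", "float32"]},
        "voxel_size_um": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "effective_config": {"type": "object"}
  }
}
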