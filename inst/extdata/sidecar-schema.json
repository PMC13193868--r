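{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "octrao OCT volume sidecar",
  "description": "Geometry and manual-segmentation sidecar accompanying a multi-page 8-bit grayscale TIFF (one page per B-scan, pages ordered by y offset, rows = depth with the vitreous at the top). Row/column indices are 0-based; a boundary value b places the interface at the top edge of row b, so compartments are half-open [upper, lower). Missing boundary positions are encoded as null.",
  "type": "object",
  "required": ["schema_version", "patient_id", "laterality", "eye_role",
               "axial_um_per_px", "lateral_um_per_px", "y_offsets_mm",
               "boundaries"],
  "properties": {
    "schema_version": {"const": 1},
    "patient_id": {"type": "string"},
    "laterality": {"enum": ["OD", "OS"]},
    "eye_role": {"enum": ["CRAO", "FELLOW"]},
    "axial_um_per_px": {"type": "number", "exclusiveMinimum": 0},
    "lateral_um_per_px": {"type": "number", "exclusiveMinimum": 0},
    "quality_db": {"type": ["number", "null"]},
    "y_offsets_mm": {
      "type": "array",
      "items": {"type": "number"},
      "description": "strictly increasing; positive = superior to the fovea"
    },
    "boundaries": {
      "type": "array",
      "description": "one entry per TIFF page, same order",
      "items": {
        "type": "object",
        "required": ["ilm", "opl_onl", "bm"],
        "properties": {
          "ilm": {"type": "array", "items": {"type": ["number", "null"]}},
          "opl_onl": {"type": "array", "items": {"type": ["number", "null"]}},
          "bm": {"type": "array", "items": {"type": ["number", "null"]}}
        }
      }
    }
  }
}
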