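{
  "instrument_id": "scl90r_somatization",
  "version": "1.0",
  "label": "SCL-90-R somatization subscale",
  "items": ["scl_som_01", "scl_som_02", "scl_som_03", "scl_som_04",
            "scl_som_05", "scl_som_06", "scl_som_07", "scl_som_08",
            "scl_som_09", "scl_som_10", "scl_som_11", "scl_som_12"],
  "response_min": 0,
  "response_max": 4,
  "reverse_coded": [],
  "subscales": {
    "total": ["scl_som_01", "scl_som_02", "scl_som_03", "scl_som_04",
              "scl_som_05", "scl_som_06", "scl_som_07", "scl_som_08",
              "scl_som_09", "scl_som_10", "scl_som_11", "scl_som_12"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "12 somatic-symptom items rated 0 (not at all) to 4 (extremely)."
}
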