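{
  "instrument_id": "pds_symptoms",
  "version": "1.0",
  "label": "Posttraumatic Stress Diagnostic Scale, Part 3 symptom severity",
  "items": ["pds_sym_01", "pds_sym_02", "pds_sym_03", "pds_sym_04",
            "pds_sym_05", "pds_sym_06", "pds_sym_07", "pds_sym_08",
            "pds_sym_09", "pds_sym_10", "pds_sym_11", "pds_sym_12",
            "pds_sym_13", "pds_sym_14", "pds_sym_15", "pds_sym_16",
            "pds_sym_17"],
  "response_min": 0,
  "response_max": 3,
  "reverse_coded": [],
  "subscales": {
    "total": ["pds_sym_01", "pds_sym_02", "pds_sym_03", "pds_sym_04",
              "pds_sym_05", "pds_sym_06", "pds_sym_07", "pds_sym_08",
              "pds_sym_09", "pds_sym_10", "pds_sym_11", "pds_sym_12",
              "pds_sym_13", "pds_sym_14", "pds_sym_15", "pds_sym_16",
              "pds_sym_17"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "17 DSM-IV PTSD symptom frequency items rated 0 (not at all or only one time) to 3 (5 or more times a week / almost always); severity total 0-51."
}
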