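{
  "instrument_id": "hscl25",
  "version": "1.0",
  "label": "Hopkins Symptom Checklist, 25-item version",
  "items": ["hscl_01", "hscl_02", "hscl_03", "hscl_04", "hscl_05",
            "hscl_06", "hscl_07", "hscl_08", "hscl_09", "hscl_10",
            "hscl_11", "hscl_12", "hscl_13", "hscl_14", "hscl_15",
            "hscl_16", "hscl_17", "hscl_18", "hscl_19", "hscl_20",
            "hscl_21", "hscl_22", "hscl_23", "hscl_24", "hscl_25"],
  "response_min": 1,
  "response_max": 4,
  "reverse_coded": [],
  "subscales": {
    "anxiety": ["hscl_01", "hscl_02", "hscl_03", "hscl_04", "hscl_05",
                "hscl_06", "hscl_07", "hscl_08", "hscl_09", "hscl_10"],
    "depression": ["hscl_11", "hscl_12", "hscl_13", "hscl_14", "hscl_15",
                   "hscl_16", "hscl_17", "hscl_18", "hscl_19", "hscl_20",
                   "hscl_21", "hscl_22", "hscl_23", "hscl_24", "hscl_25"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "Part I: 10 anxiety items; Part II: 15 depression items; all rated 1 (not at all) to 4 (extremely)."
}
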