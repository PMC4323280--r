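{
  "instrument_id": "esi",
  "version": "1.0",
  "label": "Everyday Stressors Index",
  "items": ["esi_01", "esi_02", "esi_03", "esi_04", "esi_05", "esi_06",
            "esi_07", "esi_08", "esi_09", "esi_10", "esi_11", "esi_12",
            "esi_13", "esi_14", "esi_15", "esi_16", "esi_17", "esi_18",
            "esi_19", "esi_20"],
  "response_min": 0,
  "response_max": 3,
  "reverse_coded": [],
  "subscales": {
    "total": ["esi_01", "esi_02", "esi_03", "esi_04", "esi_05", "esi_06",
              "esi_07", "esi_08", "esi_09", "esi_10", "esi_11", "esi_12",
              "esi_13", "esi_14", "esi_15", "esi_16", "esi_17", "esi_18",
              "esi_19", "esi_20"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "20 items rated 0 (not bothered at all) to 3 (bothered a great deal)."
}
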