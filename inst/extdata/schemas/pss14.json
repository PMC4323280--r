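{
  "instrument_id": "pss14",
  "version": "1.0",
  "label": "Perceived Stress Scale, 14-item version",
  "items": ["pss14_01", "pss14_02", "pss14_03", "pss14_04", "pss14_05",
            "pss14_06", "pss14_07", "pss14_08", "pss14_09", "pss14_10",
            "pss14_11", "pss14_12", "pss14_13", "pss14_14"],
  "response_min": 0,
  "response_max": 4,
  "reverse_coded": ["pss14_04", "pss14_05", "pss14_06", "pss14_07",
                    "pss14_09", "pss14_10", "pss14_13"],
  "subscales": {
    "total": ["pss14_01", "pss14_02", "pss14_03", "pss14_04", "pss14_05",
              "pss14_06", "pss14_07", "pss14_08", "pss14_09", "pss14_10",
              "pss14_11", "pss14_12", "pss14_13", "pss14_14"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "The seven positively worded items are reverse coded before summation; the standard published positive-item set is the default and may be overridden for translations with different item order."
}
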