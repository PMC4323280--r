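{
  "instrument_id": "pss4",
  "version": "1.0",
  "label": "Perceived Stress Scale, 4-item short form (embedded in the KINDEX)",
  "items": ["pss4_1", "pss4_2", "pss4_3", "pss4_4"],
  "response_min": 0,
  "response_max": 4,
  "reverse_coded": ["pss4_2", "pss4_3"],
  "subscales": {
    "total": ["pss4_1", "pss4_2", "pss4_3", "pss4_4"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "Which four of the fourteen PSS items form the short form is schema-configurable; the default follows the standard published PSS-4 (two positively worded items reverse coded)."
}
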