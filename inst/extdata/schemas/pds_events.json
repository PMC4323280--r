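{
  "instrument_id": "pds_events",
  "version": "1.0",
  "label": "Posttraumatic Stress Diagnostic Scale, Part 1 traumatic event checklist",
  "items": ["pds_event_01", "pds_event_02", "pds_event_03", "pds_event_04",
            "pds_event_05", "pds_event_06", "pds_event_07", "pds_event_08",
            "pds_event_09", "pds_event_10", "pds_event_11", "pds_event_12"],
  "response_min": 0,
  "response_max": 1,
  "reverse_coded": [],
  "subscales": {
    "total": ["pds_event_01", "pds_event_02", "pds_event_03", "pds_event_04",
              "pds_event_05", "pds_event_06", "pds_event_07", "pds_event_08",
              "pds_event_09", "pds_event_10", "pds_event_11", "pds_event_12"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "Scored as a count of endorsed event types (0-12). Parts 2 (criterion A2) and 4 (functional interference) are recorded verbatim upstream but not scored: no composite uses them."
}
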