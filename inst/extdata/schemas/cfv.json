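{
  "instrument_id": "cfv",
  "version": "1.0",
  "label": "Checklist of Family Violence (synthetic default item layout)",
  "items": ["cfv_phy_1", "cfv_phy_2", "cfv_phy_3", "cfv_phy_4", "cfv_phy_5",
            "cfv_phy_6", "cfv_phy_7", "cfv_phy_8", "cfv_phy_9",
            "cfv_ver_1", "cfv_ver_2", "cfv_ver_3", "cfv_ver_4",
            "cfv_sex_1", "cfv_sex_2",
            "cfv_wit_1", "cfv_wit_2", "cfv_wit_3",
            "cfv_neg_1", "cfv_neg_2"],
  "response_min": 0,
  "response_max": 1,
  "reverse_coded": [],
  "subscales": {
    "physical": ["cfv_phy_1", "cfv_phy_2", "cfv_phy_3", "cfv_phy_4",
                 "cfv_phy_5", "cfv_phy_6", "cfv_phy_7", "cfv_phy_8",
                 "cfv_phy_9"],
    "verbal_emotional": ["cfv_ver_1", "cfv_ver_2", "cfv_ver_3", "cfv_ver_4"],
    "sexual": ["cfv_sex_1", "cfv_sex_2"],
    "witnessed": ["cfv_wit_1", "cfv_wit_2", "cfv_wit_3"],
    "neglect": ["cfv_neg_1", "cfv_neg_2"]
  },
  "scoring_rule": "sum over items after reverse coding",
  "missing_policy": "complete_case",
  "notes": "Per-subscale item counts are NOT authoritative: the published instrument does not fix them here. Defaults are chosen so attainable subscale maxima are at least the maxima observed in validation samples (physical >= 9, witnessed >= 3, verbal-emotional >= 4, total >= 15); override the schema to match a specific edition."
}
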