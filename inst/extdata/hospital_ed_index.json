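{
  "risk_items": [
    "pneumonia",
    "urinary_tract_infection",
    "stasis_ulcer",
    "unintended_weight_loss",
    "status_decline_90d",
    "falls",
    "renal_failure",
    "emphysema",
    "cancer",
    "wound_care",
    "iv_infusion",
    "injection_medication",
    "daily_nurse_monitoring",
    "unscheduled_md_visit",
    "fever",
    "nine_plus_medications"
  ],
  "slot_items": ["fever", "nine_plus_medications"],
  "protective_items": ["alzheimers", "day_care"],
  "cap": 6,
  "prior_use_extension": true
}
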