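{
  "tests": [
    {"id": "IT0", "label": "point-of-care albuminuria test", "role": "index",
     "parent": null, "target_disease": "M_albuminuria"},
    {"id": "IT1", "label": "dipstick, cutoff 3.4 mg/mmol", "role": "index",
     "parent": "IT0", "target_disease": "M_albuminuria"},
    {"id": "IT2", "label": "dipstick, cutoff 2.65 mg/mmol", "role": "index",
     "parent": "IT0", "target_disease": "M_albuminuria"},
    {"id": "RT0", "label": "laboratory ACR", "role": "reference",
     "parent": null, "target_disease": "M_albuminuria"},
    {"id": "RT1", "label": "laboratory ACR, cutoff 3.4 mg/mmol",
     "role": "reference", "parent": "RT0", "target_disease": "M_albuminuria"},
    {"id": "RT2", "label": "laboratory ACR, cutoff 2.65 mg/mmol",
     "role": "reference", "parent": "RT0", "target_disease": "M_albuminuria"}
  ],
  "diseases": [
    {"id": "M_albuminuria", "label": "albuminuria"}
  ]
}
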