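{
  "_comment": "SYNTHETIC placeholder reference dose rates (Gy/s) per radiation type. The literature table behind the original comparison is not public; replace these with curated values before drawing any scientific conclusion.",
  "gamma":    {"rate_Gy_per_s": 0.01,  "placeholder": true},
  "xray":     {"rate_Gy_per_s": 0.05,  "placeholder": true},
  "proton":   {"rate_Gy_per_s": 1.0,   "placeholder": true},
  "ion":      {"rate_Gy_per_s": 0.5,   "placeholder": true}
}
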