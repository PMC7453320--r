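{
  "n_participants": 6,
  "n_days": 28,
  "prompts_per_day": 2,
  "relapse_rate": 1,
  "p_resp": 0.7,
  "seed": 20240101,
  "start_date": "2024-01-01"
}
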