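{
  "participant_id": "demo",
  "relevance": {
    "voices": 3,
    "voices_distress": 3,
    "suspicious": 3,
    "persecution": 3,
    "reference": 3,
    "grandiosity": 3,
    "thought_disorder": 3,
    "anxious": 2,
    "sad": 1,
    "hopeless": 1,
    "stressed": 1,
    "sleep": 2
  },
  "thresholds": {
    "single_point_rise": 0.4,
    "consecutive_rise": 0.25
  },
  "baseline_days": 3
}
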