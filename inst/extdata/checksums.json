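{
  "model_prioritisation.json": "0abb7c3a1c3276831131a9f661cde655",
  "model_gap.json": "002c0e5a76ab6fed6fa8df50c667ee94",
  "overall_scores.csv": "9c3dee1b826f1dcf5777297bfe34e3c4",
  "category_scores.csv": "b14511d539c34f68fe20cd958fecea01",
  "gap_scores.csv": "3694a5473e664eb63e290685f3b6b5ea"
}
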