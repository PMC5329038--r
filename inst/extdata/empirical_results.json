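{
  "description": "Observed answer distribution of 72 five-to-six-year-old children on second-order false-belief questions (17 stories of two types), packaged as a model-comparison fixture. provenance: 'printed' = transcribed published value; 'reconstructed' = derived integer counts, never printed.",
  "overall": {
    "provenance": "printed",
    "correct_percent": 17,
    "wrong_percent": 83
  },
  "wrong_answers": {
    "n_wrong": 119,
    "percent": {
      "provenance": "printed",
      "first_order": 65,
      "zero_order": 29,
      "dont_know": 6
    },
    "counts": {
      "provenance": "reconstructed",
      "note": "unique non-negative integer triple summing to 119 that reproduces the published goodness-of-fit statistic 64.76 to two decimals; 78/119 = 65.5% rounds to 66, while 65% was printed",
      "first_order": 78,
      "zero_order": 34,
      "dont_know": 7
    }
  },
  "goodness_of_fit": {
    "provenance": "printed",
    "statistic": 64.76,
    "df": 2,
    "n": 119,
    "p": "< 0.001"
  },
  "correct_percent_by_story_type": {
    "provenance": "printed",
    "note": "standard errors in *_se",
    "three_locations": { "control": 95, "control_se": 0.02, "first_order": 81, "first_order_se": 0.05, "second_order": 17, "second_order_se": 0.05 },
    "three_goals":     { "control": 96, "control_se": 0.01, "first_order": 93, "first_order_se": 0.03, "second_order": 17, "second_order_se": 0.05 }
  },
  "wrong_percent_by_story_type": {
    "provenance": "printed",
    "note": "shares of all answers, not of wrong answers; reported for context, not used for calibration",
    "three_locations": { "first_order": 51, "zero_order": 28 },
    "three_goals":     { "first_order": 57, "zero_order": 19 }
  }
}
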