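{
  "title": "hostresist results record",
  "sections": {
    "treatment_effect": {
      "required": {
        "log_odds": "number",
        "statistic": "number",
        "p_value": "number",
        "note": "string"
      }
    },
    "survival": {
      "required": {}
    },
    "life_history": {
      "required": {
        "mean_total_eggs": "object",
        "hatch_proportion": "object",
        "fecundity_treatment_lr": "object",
        "hatch_treatment_lr": "object"
      }
    }
  }
}
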