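{
  "description": "Aggregate counts of the development cohort, reconstructed from published group sizes and group-level LNM rates",
  "n": 306,
  "n_lnm_pos": 102,
  "n_lnm_neg": 204,
  "proposed": [
    {
      "risk_group": "low",
      "lnm_pos": 2,
      "lnm_neg": 109
    },
    {
      "risk_group": "intermediate",
      "lnm_pos": 35,
      "lnm_neg": 75
    },
    {
      "risk_group": "high",
      "lnm_pos": 65,
      "lnm_neg": 20
    }
  ],
  "eau": [
    {
      "risk_group": "low",
      "lnm_pos": 0,
      "lnm_neg": 31
    },
    {
      "risk_group": "intermediate",
      "lnm_pos": 10,
      "lnm_neg": 45
    },
    {
      "risk_group": "high",
      "lnm_pos": 92,
      "lnm_neg": 128
    }
  ],
  "feature_marginals": {
    "wpoi": [0.0261437908496732, 0.173202614379085, 0.441176470588235, 0.359477124183007],
    "lhr": [0.57516339869281, 0.300653594771242, 0.124183006535948],
    "lvi": 0.366013071895425,
    "pni": 0.277777777777778
  },
  "pt_marginals": {
    "pT1": 0.356209150326797,
    "pT2": 0.411764705882353,
    "pT3": 0.23202614379085
  },
  "age_mean": 67.8,
  "age_sd": 10.6
}
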