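{
  "huJ591-like": {
    "label": "huJ591-like",
    "amp_fast": 17.5,
    "rate_fast": -0.105,
    "amp_slow": 18.0,
    "rate_slow": -0.0115,
    "provenance": "Synthetic parameter set emulating the fast serum clearance reported for an 89Zr-labelled anti-PSMA IgG in metastatic prostate cancer (fast-phase half-life 6.6 h, terminal half-life 60 h, C0 = 35.5 %IA/L). Not a digitized fit of published data; chosen to reproduce the qualitative clearance ordering (smallest plasma AUC of the three bundled profiles) of the literature curves."
  },
  "trastuzumab-like": {
    "label": "trastuzumab-like",
    "amp_fast": 15.0,
    "rate_fast": -0.1,
    "amp_slow": 20.0,
    "rate_slow": -0.0075,
    "provenance": "Synthetic parameter set emulating intermediate serum clearance of an 89Zr-labelled anti-HER2 IgG (fast-phase half-life 6.9 h, terminal half-life 92 h, C0 = 35 %IA/L). Not a digitized fit of published data."
  },
  "pertuzumab-like": {
    "label": "pertuzumab-like",
    "amp_fast": 13.0,
    "rate_fast": -0.08,
    "amp_slow": 22.0,
    "rate_slow": -0.0045,
    "provenance": "Synthetic parameter set emulating slow serum clearance of an 89Zr-labelled anti-HER2 IgG (fast-phase half-life 8.7 h, terminal half-life 154 h, C0 = 35 %IA/L; largest plasma AUC of the three bundled profiles). Not a digitized fit of published data."
  }
}
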