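{
  "site_classes": [{"n": 4, "KH": 2e-07, "g_weight": 0.25}],
  "KOC": 0.05,
  "k_on": 1e+10,
  "k_close": 3.7
}
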