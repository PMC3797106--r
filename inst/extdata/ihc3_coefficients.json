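{
  "source": "IHC4 prognostic score of Cuzick et al. (2011), J Clin Oncol 29(32):4273-8, restricted to HER2-negative tumors by dropping the HER2 term (IHC3)",
  "multiplier": 94.7,
  "er10": -0.1,
  "pr10": -0.079,
  "ki67": 0.24,
  "ki67_transform": "log(1 + 10 * ki67_fraction / ki67_rescale)"
}
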