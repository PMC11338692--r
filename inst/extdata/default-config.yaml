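# Reference configuration: the parameter set used throughout the analyses.
params:
  d_E0: 0.5   # baseline egg mortality (inverse proxy for baseline male care)
  d_A0: 0.5   # baseline adult male mortality
  r_0: 0.5    # baseline fertilization success
  b: 100      # female gametes available per reproductive episode
  "n": 5      # future reproductive episodes in the truncated lifetime sum
              # (quoted: bare n is a YAML 1.1 boolean)
regime:
  kind: unconstrained
  per_trait_level: 0.5
  budget: 0.5
sweep:
  parameter: d_E0
  grid_size: 99
seed: 1
outdir: "."
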