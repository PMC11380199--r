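# Default Bayesian points-framework odds of pathogenicity per evidence
# strength (benign odds are reciprocals). Overrides pin individual codes,
# e.g. to reproduce a source that rounds its odds.
very_strong: 350
strong: 18.7
moderate: 4.33
supporting: 2.08
overrides:
  PS3: 18.8
  BS3: 0.053
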