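area:
  labels: [urban, rural]
  role: covariate
educ:
  labels: [none, primary]
  role: covariate
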