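# Small demonstration configuration: 2,000 synthetic messages, 10
# topics, 4 themes. Completes in a few minutes on one CPU.
seed: 42
generator:
  n_users: 400
  n_messages: 2000
correction:
  sample_size: 30
topics:
  k: 10
  beta: 0.01
  iterations: 400
  burn_in: 100
  min_author_frac: 0.05
themes:
  t: 4
prevalence:
  rates:
    breast cancer: 0.024
    asthma: 0.085
    diabetes: 0.17
    stroke: 0.03
    heart disease: 0.19
    hypertension: 0.36
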