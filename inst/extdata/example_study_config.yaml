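# Example study configuration (all data synthetic).
schema: study1
directional_hypotheses:
  strength: '+'
  reciprocation: '+'
  gender_giving: '-'
  gender_receiving: '+'
group_codes:
  year9: 0
  year12: 1
n_perm: 10000
n_boot: 1000
alpha: 0.05
seed: 7
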