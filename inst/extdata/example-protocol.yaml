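# Example session: initially active cell in a novel environment with a
# short dendritic induction while the novelty signal is still strong.
preset: novel_induction
n_laps: 40
novelty: true
seed: 1
weights: {generator: single_bump, total: 2, delta: 0.5, bump_index: 5}
inductions:
  - {kind: dendritic_current, region: [0.765, 0.215],
     first_lap: 5, n_laps: 4, amplitude: 25}
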