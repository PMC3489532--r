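# Example simulation config: one charge-2 block matching the package's
# reference conditions (70% incorrect identifications; incorrect scores from
# a shifted Gamma, correct scores from a Normal; decoys drawn from the
# incorrect component, sized like the incorrect-target population so the
# decoy-ratio FDR estimator is calibrated).
- charge: 2
  pi0: 0.7
  n_targets: 10000
  n_decoys: 7000
  negative: {kind: shifted_gamma, alpha: 4, beta: 2, shift: -3}
  positive: {kind: normal, mu: 3, sigma: 1}
  discrete:
    nmc:
      levels: [0, 1, 2]
      p_incorrect: [0.404, 0.45, 0.146]
      p_correct: [0.926, 0.06, 0.014]
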