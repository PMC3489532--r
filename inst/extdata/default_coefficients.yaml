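# Illustrative placeholder discriminant coefficients, keyed by engine and
# precursor charge. These are NOT published values: the originally trained
# per-charge coefficients were never printed, so real analyses must supply
# coefficients trained on a controlled mixture, or estimate them from the
# data with the adaptive fit. These placeholders merely have the expected
# signs (reward XCorr/deltaCn/logDot/deltaDot, penalize a poor SpRank) and
# sensible magnitudes for smoke tests and examples.
sequest:
  "1": {intercept: -4.0, weights: {XCorr: 2.5, deltaCn: 8.0, SpRank: -0.20}}
  "2": {intercept: -4.5, weights: {XCorr: 2.0, deltaCn: 8.0, SpRank: -0.20}}
  "3": {intercept: -5.0, weights: {XCorr: 1.5, deltaCn: 8.0, SpRank: -0.20}}
tandem:
  "1": {intercept: -3.0, weights: {logDot: 1.0, deltaDot: 4.0}}
  "2": {intercept: -3.5, weights: {logDot: 1.0, deltaDot: 4.0}}
  "3": {intercept: -4.0, weights: {logDot: 1.0, deltaDot: 4.0}}
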