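# Default vulnerability scoring scheme.
# Thresholds give, per variable and sex, the maximal "low" score and the
# bounds of the "adequate" band; "high" starts at adq_max + 1. EQ-A and
# EQ-C are sex-specific, SWB and EQ-R are not. Instrument bounds: SWLS
# totals 5-35, TMMS subscales 8-40.
thresholds:
  swb:
    male:   {low_max: 14, adq_min: 15, adq_max: 15, high_min: 16}
    female: {low_max: 14, adq_min: 15, adq_max: 15, high_min: 16}
  eqa:
    male:   {low_max: 21, adq_min: 22, adq_max: 32, high_min: 33}
    female: {low_max: 24, adq_min: 25, adq_max: 35, high_min: 36}
  eqc:
    male:   {low_max: 25, adq_min: 26, adq_max: 35, high_min: 36}
    female: {low_max: 23, adq_min: 24, adq_max: 34, high_min: 35}
  eqr:
    male:   {low_max: 23, adq_min: 24, adq_max: 34, high_min: 35}
    female: {low_max: 23, adq_min: 24, adq_max: 34, high_min: 35}
instrument_bounds:
  swb: [5, 35]
  eqa: [8, 40]
  eqc: [8, 40]
  eqr: [8, 40]
# Representative points per level: male-range midpoints rescaled per
# variable so the all-low state totals 80 and the all-high state 140.
level_scores:
  swb: {low: 20, adequate: 25.15625, high: 35}
  eqa: {low: 20, adequate: 28.522727272727273, high: 35}
  eqc: {low: 20, adequate: 29.767441860465116, high: 35}
  eqr: {low: 20, adequate: 29.204545454545453, high: 35}
band_cutoffs:
  low_range: [100, 120]
  complete_min: 120
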