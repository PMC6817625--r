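groups:
- sex: M
  country: BR
  'n': 40
  age_mean: 23.7
  age_sd: 3.67
  height_mean: 176.0
  height_sd: 7.0
  weight_mean: 75.0
  weight_sd: 10.0
  ratio_mean: 0.75
  ratio_sd: 0.05
  f0_speech_mean: -22.15
  f0_speech_sd: 2.13
  f0_singing_mean: -19.71
  f0_singing_sd: 2.49
  range_speech_mean: 11.98
  range_speech_sd: 2.52
  range_singing_mean: 14.65
  range_singing_sd: 2.52
  vtl_speech_mean: 17.32
  vtl_speech_sd: 0.49
  vtl_singing_mean: 16.8
  vtl_singing_sd: 0.53
  attract_speech_mean: 3.48
  attract_speech_sd: 0.66
  attract_singing_mean: 3.11
  attract_singing_sd: 0.72
  soi_mean: 45.0
  soi_sd: 15.0
  liking_mean: 6.0
  liking_sd: 2.2
- sex: M
  country: CZ
  'n': 33
  age_mean: 22.45
  age_sd: 2.35
  height_mean: 181.0
  height_sd: 7.0
  weight_mean: 80.0
  weight_sd: 11.0
  ratio_mean: 0.75
  ratio_sd: 0.05
  f0_speech_mean: -22.63
  f0_speech_sd: 1.84
  f0_singing_mean: -20.51
  f0_singing_sd: 2.26
  range_speech_mean: 11.02
  range_speech_sd: 2.9
  range_singing_mean: 14.24
  range_singing_sd: 2.42
  vtl_speech_mean: 17.57
  vtl_speech_sd: 0.51
  vtl_singing_mean: 17.18
  vtl_singing_sd: 0.64
  attract_speech_mean: 3.48
  attract_speech_sd: 0.66
  attract_singing_mean: 3.11
  attract_singing_sd: 0.72
  soi_mean: 40.0
  soi_sd: 14.0
  liking_mean: 6.0
  liking_sd: 2.2
- sex: F
  country: BR
  'n': 44
  age_mean: 23.91
  age_sd: 4.99
  height_mean: 163.0
  height_sd: 6.0
  weight_mean: 60.0
  weight_sd: 9.0
  ratio_mean: 0.73
  ratio_sd: 0.05
  f0_speech_mean: -13.19
  f0_speech_sd: 1.28
  f0_singing_mean: -10.5
  f0_singing_sd: 2.05
  range_speech_mean: 14.25
  range_speech_sd: 4.23
  range_singing_mean: 15.7
  range_singing_sd: 3.25
  vtl_speech_mean: 14.18
  vtl_speech_sd: 0.3
  vtl_singing_mean: 13.93
  vtl_singing_sd: 0.38
  attract_speech_mean: 3.89
  attract_speech_sd: 0.65
  attract_singing_mean: 3.82
  attract_singing_sd: 0.73
  soi_mean: 35.0
  soi_sd: 14.0
  liking_mean: 6.5
  liking_sd: 2.2
- sex: F
  country: CZ
  'n': 35
  age_mean: 22.37
  age_sd: 2.57
  height_mean: 168.0
  height_sd: 6.0
  weight_mean: 63.0
  weight_sd: 9.0
  ratio_mean: 0.73
  ratio_sd: 0.05
  f0_speech_mean: -13.0
  f0_speech_sd: 1.53
  f0_singing_mean: -10.07
  f0_singing_sd: 2.08
  range_speech_mean: 12.97
  range_speech_sd: 3.55
  range_singing_mean: 15.74
  range_singing_sd: 2.96
  vtl_speech_mean: 14.38
  vtl_speech_sd: 0.39
  vtl_singing_mean: 13.95
  vtl_singing_sd: 0.34
  attract_speech_mean: 3.89
  attract_speech_sd: 0.65
  attract_singing_mean: 3.82
  attract_singing_sd: 0.73
  soi_mean: 32.0
  soi_sd: 13.0
  liking_mean: 6.5
  liking_sd: 2.2
cross_display:
  M:
    f0: 0.8
    range: 0.408
    vtl: 0.808
    attract: 0.72
  F:
    f0: 0.607
    range: 0.16
    vtl: 0.764
    attract: 0.674
extra_correlations:
  height_weight: 0.5
  weight_vtl: 0.3
  height_vtl: 0.3
  f0_vtl_within: -0.5
  f0_vtl_cross: -0.4
structural:
  M:
    attract_speech:
      speech_f0_st: -0.3
      speech_range_st: 0.2
      weight_kg: 0.3
      age: -0.15
    attract_singing:
      singing_f0_st: -0.15
      weight_kg: 0.3
    soi_total:
      speech_f0_st: -0.25
      singing_f0_st: 0.2
      attract_speech: 0.25
  F:
    attract_speech:
      speech_f0_st: 0.3
    attract_singing:
      singing_f0_st: 0.3
      weight_kg: -0.15
    soi_total:
      speech_vtl_cm: -0.2
      singing_vtl_cm: 0.2
liking_structural:
  M:
    attract_singing: 0.3
  F:
    attract_singing: 0.3
rating:
  target_alpha: 0.79
  scale_bounds:
  - 1
  - 7
  rater_sd: 0.3
  raters:
    M:
      BR: 59
      CZ: 47
    F:
      BR: 51
      CZ: 46
speed_of_sound_cm_s: 33500.0
pd_eps: 1.0e-06
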