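mediator_basis: F0
variables:
  age: exogenous
  height_cm: exogenous
  weight_kg: exogenous
  wsr: exogenous
  speech_f0_st: mediator
  singing_f0_st: mediator
  speech_range_st: mediator
  singing_range_st: mediator
  attract_speech: outcome
  attract_singing: outcome
  soi_total: final
regressions:
  attract_singing:
  - speech_f0_st
  - singing_f0_st
  - speech_range_st
  - singing_range_st
  - age
  - height_cm
  - weight_kg
  - wsr
  attract_speech:
  - speech_f0_st
  - singing_f0_st
  - speech_range_st
  - singing_range_st
  - age
  - height_cm
  - weight_kg
  - wsr
  singing_f0_st:
  - age
  - height_cm
  - weight_kg
  - wsr
  singing_range_st:
  - age
  - height_cm
  - weight_kg
  - wsr
  soi_total:
  - speech_f0_st
  - singing_f0_st
  - speech_range_st
  - singing_range_st
  - attract_speech
  - attract_singing
  speech_f0_st:
  - age
  - height_cm
  - weight_kg
  - wsr
  speech_range_st:
  - age
  - height_cm
  - weight_kg
  - wsr
covariances:
- - age
  - height_cm
- - age
  - weight_kg
- - age
  - wsr
- - height_cm
  - weight_kg
- - height_cm
  - wsr
- - weight_kg
  - wsr
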