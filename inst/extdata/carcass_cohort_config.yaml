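# Carrier vs non-carrier progeny cohort: cold carcass weight summary
# used to parameterize the regression-stage simulation.
trait: cold carcass weight
meanKg: 495.9
sdKg: 65.3
effectKg: 33.9
seKg: 9.4
nNonCarrier: 86
nCarrier: 85
ageSlopeKgPerDay: 0.5
ageMeanDays: 900
ageSdDays: 30
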