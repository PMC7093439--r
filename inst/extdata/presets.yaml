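# Drug-effect preset registry.
#
# Scales are full-effect values reached along the onset time-course; s_amp
# values are calibrated with calibrate_preset() so that the noise-free
# pipeline reproduces each drug's reported change in stabilisation-
# normalised net power output (target_delta_pp, drug minus vehicle in
# percentage points) at its documented maximal-response time
# (t_max_effect_min, minutes of treatment).  Onset constants are chosen so
# first-significant and maximal-effect times match the reported
# time-courses: fast for dobutamine, intermediate for digoxin, slow for
# verapamil/flecainide/atenolol, and biphasic (transient) for
# isoprenaline.  The two vehicles are modelled identically.

vehicle_kh:
  name: vehicle_kh
  s_amp: 1.0
  t_max_effect_min: 30
  target_delta_pp: 0.0
  vehicle: vehicle_kh

vehicle_dmso:
  name: vehicle_dmso
  s_amp: 1.0
  t_max_effect_min: 30
  target_delta_pp: 0.0
  vehicle: vehicle_kh

digoxin:
  name: digoxin
  s_amp: 1.278407
  s_relax: 1.0
  s_pas: 1.0
  tau_on_min: 10
  t_max_effect_min: 35
  target_delta_pp: 27.0
  vehicle: vehicle_dmso
  dose: "1 uM"

dobutamine:
  name: dobutamine
  s_amp: 2.571860
  s_relax: 0.75
  s_pas: 1.0
  tau_on_min: 3
  t_max_effect_min: 10
  target_delta_pp: 20.0
  vehicle: vehicle_dmso
  dose: "1 uM"

isoprenaline:
  name: isoprenaline
  s_amp: 2.495328
  s_relax: 0.75
  s_pas: 1.0
  tau_on_min: 5
  tau_off_min: 25
  t_max_effect_min: 10
  target_delta_pp: 14.0
  vehicle: vehicle_kh
  dose: "30 nM"

verapamil:
  name: verapamil
  s_amp: 0.809971
  s_relax: 1.0
  s_pas: 1.0
  tau_on_min: 20
  t_max_effect_min: 45
  target_delta_pp: -17.0
  vehicle: vehicle_kh
  dose: "1 uM"

flecainide:
  name: flecainide
  s_amp: 0.814957
  s_relax: 1.0
  s_pas: 0.90
  tau_on_min: 20
  t_max_effect_min: 40
  target_delta_pp: -16.0
  vehicle: vehicle_kh
  dose: "3 uM"

atenolol:
  name: atenolol
  s_amp: 0.854684
  s_relax: 1.0
  s_pas: 1.0
  tau_on_min: 20
  t_max_effect_min: 45
  target_delta_pp: -13.0
  vehicle: vehicle_kh
  dose: "20 uM"
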