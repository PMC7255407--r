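# Species-level response parameters for the maize simulator.
# Piecewise-linear temperature responses are given as parallel lists of
# breakpoints (deg C) and factors in [0, 1]; values outside the breakpoint
# range take the nearest endpoint factor.  Editing this file is the supported
# way to emulate manual adjustment of the temperature responses.
tbase: 8.0
photoperiod_threshold: 12.5
emergence_tt: 45.0
prftc:
  temp: [6.2, 16.5, 33.0, 44.0]
  factor: [0.0, 1.0, 1.0, 0.0]
rgfil:
  temp: [5.5, 16.0, 39.0, 48.5]
  factor: [0.0, 1.0, 1.0, 0.0]
# Leaf-number model: total leaves = tlno_base + P1 / leaf_init_tt
tlno_base: 18.6
leaf_init_tt: 48.2
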