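# Calibrated model defaults (see the methods vignette for rationale).
# Potentials in mV, currents in pA, conductances in mS/uF, times in ms,
# kernel sigmas and the sheet extent in mm.
geometry:
  n_side: 48          # desk-scale default; the full-scale sheet uses 120
  extent: 5.0         # sheet side, mm (rat V1 scale)
kernels:
  axon:               # soma -> dendrite connection probability
    sigma: 0.42
    amplitude: 0.3
  branch:             # dendrite -> soma (branch ownership) probability
    sigma: 0.42
    amplitude: 0.3
soma:
  a: 0.02             # adaptation rate; 1/a = 50 ms decay of somatic K current
  b: 0.2
  c: -65.0
  d: 8.0
  v_peak: 30.0
  E_inh: -75.0
dendrite:
  C_d: 20.0
  g_Ca: 4.4
  g_K: 8.0
  g_L: 2.0
  V_Ca: 120.0
  V_K: -84.0
  V_L: -60.0
  V1: -1.2
  V2: 18.0
  V3: 2.0
  V4: 30.0
  tau_d: 200.0        # slow-dendrite default; sweep range 5..500
  kappa: 0.73
  tau_syn: 5.0
  g_syn: 2.0
  E_syn: 0.0
  g_ds: 0.0125
inhibition:
  tau_I: 10.0
  drive_gain: 1.0
  g_I: 0.02
stimulus:
  const_amplitude: 2.0       # noiseless background drive
  noise_weak: 4.0            # white-noise variance anchors (pA^2 ms)
  noise_moderate: 25.0
  noise_strong: 150.0
  inhib_amplitude: 100.0     # global inhibition strong enough to silence
snapshot:
  window: 10.0
  filter_sigma: 2.0
  core_threshold: 0.5
classification:
  clustering_broken: 3.0     # clustering index floor for an intact bump
  speed_immobile: 0.03      # lattice units/ms
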