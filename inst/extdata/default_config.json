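{
  "windkessel": {
    "R": 1.72,
    "C": 0.48,
    "r": 0.105,
    "L": 0.0059
  },
  "Ts": 0.002,
  "noise": {
    "_comment": "Qproc/Rmeas are this package's calibrated defaults (steady-state vC gain 0.22 for the model above at 500 Hz); they are not published physiologic constants. Rmeas = 25 mmHg^2 matches the default 5 mmHg artifact sigma.",
    "Qproc": [1.58, 0.01],
    "Rmeas": 25
  },
  "flow": {
    "heart_rate": 60,
    "stroke_volume": 70,
    "systolic_fraction": 0.35,
    "fs": 500,
    "duration": 10
  },
  "artifact": {
    "gaussian_sigma": 5,
    "spike_times": [],
    "spike_amplitudes": [],
    "seed": 42
  },
  "settle_periods": 5,
  "spectral": {
    "window": "rectangular",
    "n_peaks": 2,
    "floor_hz": 0.25
  }
}
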