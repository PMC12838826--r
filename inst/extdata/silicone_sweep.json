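{
  "name": "silicone_sweep",
  "seed": 42,
  "snr_db": 30,
  "method": "xcorr",
  "pulse": {
    "center_frequency": 2e6,
    "fractional_bandwidth": 0.6,
    "amplitude": 1
  },
  "indenter": {
    "contact_radius_a": 0.01
  },
  "phantoms": {
    "silicone_10HA": {
      "thickness_h": 0.01,
      "sound_speed_v": 1000,
      "youngs_modulus_E": 412686,
      "poisson_ratio_nu": 0.5
    }
  },
  "loads": {
    "type": "force",
    "values_N": [0, 5, 10, 15, 20, 25, 30, 35]
  }
}
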