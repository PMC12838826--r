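{
  "description": "sonodent experiment configuration. All quantities SI (m, Pa, Hz, N) unless the key name says otherwise.",
  "fields": {
    "name": "text label for the experiment",
    "seed": "integer base seed; every noise draw derives from it",
    "sampling_rate": "Hz; optional, default 5e7 (25x the 2 MHz carrier)",
    "snr_db": "peak-signal SNR in dB, or null for noise-free simulation",
    "method": "ToF estimator: 'xcorr' (default) or 'envelope_peak'",
    "pulse": {
      "center_frequency": "carrier Hz; default 2e6",
      "fractional_bandwidth": "-6 dB width as fraction of carrier, (0,1]; default 0.6",
      "amplitude": "peak amplitude, arbitrary units; default 1"
    },
    "indenter": {
      "contact_radius_a": "flat-punch contact radius in m; default 0.01"
    },
    "phantoms": {
      "<name>": {
        "thickness_h": "resting thickness, m",
        "sound_speed_v": "longitudinal sound speed, m/s",
        "youngs_modulus_E": "Young's modulus, Pa",
        "poisson_ratio_nu": "[0, 0.5]; default 0.5",
        "attenuation_alpha": "dB/(cm MHz); default 0.5",
        "stiffening_beta": ">= 0; 0 = linear elastic; default 0",
        "inclusion": "null, or {depth_fraction, thickness_fraction, youngs_modulus_E_inc}"
      }
    },
    "loads": {
      "type": "'force' or 'pressure'",
      "values_N": "force levels in N (type 'force'); first value is the baseline",
      "values_kPa": "pressure levels in kPa (type 'pressure'); converted to force via the contact area"
    },
    "lesion": {
      "reference": "phantom name for the reference condition",
      "test": "phantom name for the test condition",
      "n_repeats": "repeated pairs per condition; default 8",
      "threshold": "minimum relative tau reduction to flag; default 0.2"
    }
  }
}
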