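{
  "seed": 1,
  "layout": {
    "n_channels": 32
  },
  "cohort": {
    "n_epochs": 6,
    "fs": 128,
    "duration": 2,
    "base_specs": [
      {
        "band": "alpha",
        "edges": [
          [1, 2],
          [3, 4],
          [5, 6],
          [7, 8]
        ],
        "strength": 0.8,
        "phase_lag": 1.5707963267949,
        "noise_sd": 0.3
      },
      {
        "band": "beta",
        "edges": [
          [9, 10],
          [11, 12],
          [13, 14]
        ],
        "strength": 0.7,
        "phase_lag": 1.0471975511966,
        "noise_sd": 0.3
      }
    ],
    "groups": [
      {
        "name": "HC",
        "n_subjects": 8,
        "attenuation": {
          "theta": 1,
          "alpha": 1,
          "beta": 1
        },
        "clinical_means": {
          "MMSE": 29
        },
        "clinical_sds": {
          "MMSE": 1
        }
      },
      {
        "name": "AD",
        "n_subjects": 8,
        "attenuation": {
          "theta": 1,
          "alpha": 0.6,
          "beta": 0.9
        },
        "clinical_means": {
          "MMSE": 21
        },
        "clinical_sds": {
          "MMSE": 3
        }
      },
      {
        "name": "DLB",
        "n_subjects": 8,
        "attenuation": {
          "theta": 1,
          "alpha": 0.6,
          "beta": 0.5
        },
        "clinical_means": {
          "MMSE": 21
        },
        "clinical_sds": {
          "MMSE": 3
        },
        "planted_rho": {
          "MMSE": -0.6
        }
      },
      {
        "name": "PDD",
        "n_subjects": 8,
        "attenuation": {
          "theta": 1,
          "alpha": 0.6,
          "beta": 0.7
        },
        "clinical_means": {
          "MMSE": 20
        },
        "clinical_sds": {
          "MMSE": 3
        }
      }
    ]
  },
  "bands": ["alpha", "beta"],
  "pt": {
    "lo": 3,
    "hi": 60,
    "step": 1
  },
  "modes": ["binary", "weighted"],
  "metrics": ["K", "C", "L", "Q"],
  "n_surrogates": 0,
  "density": {
    "n_perm": 1000
  },
  "stats": {
    "nbs_stat": "F",
    "nbs_threshold": 8,
    "n_perm": 500
  },
  "classify": {
    "groups": ["DLB", "AD"],
    "folds": 4,
    "repeats": 3
  },
  "write_epochs": false
}
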