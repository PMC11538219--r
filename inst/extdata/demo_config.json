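{
  "seed": 1,
  "stages": {
    "synthetic": true,
    "morphometry": true,
    "rheology": true,
    "qpcr": true,
    "elastica": true,
    "report": true
  },
  "spheroids": {
    "conditions": [
      {
        "name": "agarose_0.5pct",
        "mean_area_um2": 5484
      },
      {
        "name": "agarose_1pct",
        "mean_area_um2": 2669
      },
      {
        "name": "agarose_2pct",
        "mean_area_um2": 1316
      }
    ],
    "n_spheroids": 60,
    "cv_area": 0.5,
    "um_per_px": 2,
    "n_fields": 2,
    "spheroids_per_field": 30
  },
  "viability": {
    "n_live": 190,
    "n_dead": 10,
    "cell_radius_um": 6,
    "width_px": 400,
    "height_px": 400,
    "um_per_px": 1
  },
  "compression": {
    "samples": [
      {
        "name": "agarose_0.5pct",
        "E_true_pa": 3800
      },
      {
        "name": "agarose_1pct",
        "E_true_pa": 12100
      },
      {
        "name": "agarose_2pct",
        "E_true_pa": 44800
      }
    ],
    "n_replicates": 3,
    "toe_strain": 0.05,
    "max_strain": 0.4,
    "n_points": 200,
    "noise_sd_frac": 0.01
  },
  "qpcr": {
    "conditions": ["agarose_1pct", "agarose_2pct"],
    "genes": ["Ki67", "GAPDH"],
    "reference_gene": "GAPDH",
    "fold_treated": 0.23,
    "replicates": 4,
    "ct_noise_sd": 0.15
  },
  "elastica": {
    "materials": [
      {
        "name": "agarose_0.5pct",
        "E_pa": 2000
      },
      {
        "name": "agarose_1pct",
        "E_pa": 19830
      },
      {
        "name": "agarose_2pct",
        "E_pa": 99596
      }
    ],
    "nu": 0.45,
    "seed_radius_um": 5,
    "h_cavity_um": 1,
    "outer_radius_factor": 20
  }
}
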