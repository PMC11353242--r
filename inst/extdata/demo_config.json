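{
  "seed": 7,
  "cna": {
    "enabled": true,
    "bin_size": 1e6,
    "ploidy": 2,
    "n_alterations": 10,
    "alteration_length": 2e7,
    "attenuation_fraction": 0.7,
    "new_alteration_fraction": 0.3,
    "mean_count": 100,
    "dispersion": 0.05,
    "gc_linear": 0.6,
    "gc_quadratic": -2,
    "min_bins": 3,
    "alpha": 0.001,
    "n_perm": 999
  },
  "karyotype": {
    "enabled": true,
    "n_cells": 100,
    "base_count": 107,
    "rate_control": 0.02,
    "rate_knockdown": 0.005,
    "divisions": 10
  },
  "events": {
    "enabled": true,
    "n_cells": 100,
    "p_control": 0.24,
    "p_knockdown": 0.1
  },
  "tracking": {
    "enabled": true,
    "n_frames": 45,
    "interval": 2,
    "pixel_size": 0.1,
    "width": 100,
    "height": 100,
    "n_emitters": 6,
    "speed_control": 3,
    "speed_knockdown": 4.5,
    "quality_threshold": 4,
    "max_disp": 4,
    "min_duration": 5,
    "min_spots": 5
  }
}
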