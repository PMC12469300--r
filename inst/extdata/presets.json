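{
  "version": "1.0",
  "comment": "Named generator presets calibrated to published per-condition means: nuclear area and N/C ratio of U-2 OS and SAOS-2 cells with/without capsaicin, box-counting FD of AFM edge masks, nuclear Src enrichment fold. Dispersion parameters (area SD, N/C SD) are generator knobs, not published values.",
  "presets": {
    "u2os_control": {
      "nuclear_area_mean": 553.7, "nuclear_area_sd": 110.7,
      "aspect_ratio_mean": 1.5,
      "orientation_model": "uniform", "kappa": 0,
      "target_fd": 1.103, "nc_ratio_mean": 0.26611,
      "nuclear_src_fold": 1.0,
      "background_level": 100, "noise_sd": 5, "pixel_size": 0.25
    },
    "u2os_capsaicin": {
      "nuclear_area_mean": 749.1, "nuclear_area_sd": 149.8,
      "aspect_ratio_mean": 1.5,
      "orientation_model": "uniform", "kappa": 0,
      "target_fd": 1.272, "nc_ratio_mean": 0.4376,
      "nuclear_src_fold": 2.0,
      "background_level": 100, "noise_sd": 5, "pixel_size": 0.25
    },
    "u2os_capsaicin_amg": {
      "nuclear_area_mean": 553.7, "nuclear_area_sd": 110.7,
      "aspect_ratio_mean": 1.5,
      "orientation_model": "uniform", "kappa": 0,
      "target_fd": 1.045, "nc_ratio_mean": 0.26611,
      "nuclear_src_fold": 1.0,
      "background_level": 100, "noise_sd": 5, "pixel_size": 0.25
    },
    "u2os_stretch": {
      "nuclear_area_mean": 749.1, "nuclear_area_sd": 149.8,
      "aspect_ratio_mean": 1.6,
      "orientation_model": "perpendicular_biased", "kappa": 6,
      "target_fd": 1.103, "nc_ratio_mean": 0.4376,
      "nuclear_src_fold": 2.0,
      "background_level": 100, "noise_sd": 5, "pixel_size": 0.25
    },
    "saos2_control": {
      "nuclear_area_mean": 612.0, "nuclear_area_sd": 122.4,
      "aspect_ratio_mean": 1.4,
      "orientation_model": "uniform", "kappa": 0,
      "target_fd": 1.051, "nc_ratio_mean": 0.23349,
      "nuclear_src_fold": 1.0,
      "background_level": 100, "noise_sd": 5, "pixel_size": 0.25
    },
    "saos2_capsaicin": {
      "nuclear_area_mean": 827.0, "nuclear_area_sd": 165.4,
      "aspect_ratio_mean": 1.4,
      "orientation_model": "uniform", "kappa": 0,
      "target_fd": 1.029, "nc_ratio_mean": 0.19188,
      "nuclear_src_fold": 0.71,
      "background_level": 100, "noise_sd": 5, "pixel_size": 0.25
    }
  }
}
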