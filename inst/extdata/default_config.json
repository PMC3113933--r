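{
  "geometry": {
    "tank_diameter_m": 0.13,
    "impeller_diameter_m": 0.07,
    "blade_width_m": 0.02,
    "working_volume_m3": 9.8e-4,
    "fluid_density_kg_m3": 1000
  },
  "rheology": {
    "n_pl": 0.5,
    "K_s": 11.5,
    "anchor": {
      "viscosity_Pa_s": 2.0,
      "wis_percent": 12,
      "shear_rate_per_s": 50
    },
    "calibration": {
      "mean_power_target_W_m3": 1500,
      "speed_rpm": 500,
      "load_fpu_per_g_glucan": 20
    }
  },
  "correlation": {
    "K1": 346.7,
    "K2": 1.27
  },
  "composition": {
    "wis0_percent": 13,
    "glucan_frac_of_wis": 0.48,
    "initial_liquid_glucose_g_L": 29.8,
    "dilute_to_wis_percent": 10
  },
  "conditions": [
    {"impeller_speed_rpm": 25, "enzyme_load_fpu_per_g_glucan": 10, "duration_h": 96},
    {"impeller_speed_rpm": 75, "enzyme_load_fpu_per_g_glucan": 10, "duration_h": 96},
    {"impeller_speed_rpm": 150, "enzyme_load_fpu_per_g_glucan": 10, "duration_h": 96},
    {"impeller_speed_rpm": 300, "enzyme_load_fpu_per_g_glucan": 10, "duration_h": 96},
    {"impeller_speed_rpm": 500, "enzyme_load_fpu_per_g_glucan": 10, "duration_h": 96},
    {"impeller_speed_rpm": 25, "enzyme_load_fpu_per_g_glucan": 20, "duration_h": 96},
    {"impeller_speed_rpm": 75, "enzyme_load_fpu_per_g_glucan": 20, "duration_h": 96},
    {"impeller_speed_rpm": 150, "enzyme_load_fpu_per_g_glucan": 20, "duration_h": 96},
    {"impeller_speed_rpm": 300, "enzyme_load_fpu_per_g_glucan": 20, "duration_h": 96},
    {"impeller_speed_rpm": 500, "enzyme_load_fpu_per_g_glucan": 20, "duration_h": 96}
  ],
  "grid": {
    "start_h": 0,
    "end_h": 96,
    "step_h": 0.5
  },
  "noise": {
    "glucose_cv": 0.04,
    "power_cv": 0.05
  },
  "seed": 1
}
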