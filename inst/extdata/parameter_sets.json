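{
  "version": 1,
  "note": "Named generative parameter sets. delta_table entries are written by scripts/calibrate_defaults.R (detection-offset calibration anchored to the per-set target thresholds in 'anchors'); conductance of the WT sets is scaled so the +180 mV current at 3 uM Ca2+ is ~2 nA.",
  "parameter_sets": {
    "WT-HEK": {
      "conductance": 0.0746471600332769,
      "v_half_max": 125.2,
      "delta_v": 72.359,
      "slope": 22,
      "ec50": 2.9,
      "hill": 1.5,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 15.59,
      "conductance_cv": 0.3,
      "delta": 0,
      "anchors": {
        "ca": [0, 3],
        "target_mV": [125.2, 88.1],
        "protocol_stop_mV": [140, 180]
      },
      "delta_table": {
        "ca": [0, 3],
        "delta": [83.984375, 72.265625]
      }
    },
    "WT-CHO": {
      "conductance": 0.0746471600332769,
      "v_half_max": 127,
      "delta_v": 65,
      "slope": 22,
      "ec50": 2.9,
      "hill": 1.5,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 13.23,
      "conductance_cv": 0.3,
      "delta": 0,
      "anchors": {
        "ca": [0, 1, 3, 9, 100, 240],
        "target_mV": [127, 116.055, 93.673, 72.051, 62.32, 62.086],
        "protocol_stop_mV": [180, 180, 180, 180, 180, 180]
      },
      "delta_table": {
        "ca": [0, 1, 3, 9, 100, 240],
        "delta": [83.0078125, 81.0546875, 76.171875, 68.359375, 63.96484375, 63.4765625]
      }
    },
    "WT-CHO-3uM": {
      "conductance": 0.0746471600332769,
      "v_half_max": 127,
      "delta_v": 65,
      "slope": 22,
      "ec50": 2.9,
      "hill": 1.5,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 8.77,
      "conductance_cv": 0.3,
      "delta": 0,
      "anchors": {
        "ca": 3,
        "target_mV": 75,
        "protocol_stop_mV": 180
      },
      "delta_table": {
        "ca": 3,
        "delta": 49.8046875
      }
    },
    "WT-913": {
      "conductance": 0.0223941480099831,
      "v_half_max": 155.4,
      "delta_v": 72.359,
      "slope": 22,
      "ec50": 2.9,
      "hill": 1.5,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 19.94,
      "conductance_cv": 0.3,
      "delta": 0,
      "anchors": {
        "ca": 3,
        "target_mV": 118.3,
        "protocol_stop_mV": 180
      },
      "delta_table": {
        "ca": 3,
        "delta": 53.7109375
      }
    },
    "T498I": {
      "conductance": 0.0746471600332769,
      "v_half_max": 82.3,
      "delta_v": 44.274,
      "slope": 22,
      "ec50": 2.9,
      "hill": 1.5,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 13.6,
      "conductance_cv": 0.3,
      "delta": 0,
      "anchors": {
        "ca": [0, 3],
        "target_mV": [82.3, 59.6],
        "protocol_stop_mV": [140, 140]
      },
      "delta_table": {
        "ca": [0, 3],
        "delta": [71.2890625, 63.96484375]
      }
    },
    "TMEM16B-like": {
      "conductance": 0.0746471600332769,
      "v_half_max": 120,
      "delta_v": 100,
      "slope": 15,
      "ec50": 1.8,
      "hill": 2,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 10,
      "conductance_cv": 0.3,
      "delta": 0,
      "anchors": {}
    },
    "control": {
      "conductance": 0,
      "v_half_max": 185,
      "delta_v": 0,
      "slope": 12,
      "ec50": 2.9,
      "hill": 1.5,
      "tau_ms": 60,
      "leak_nS": 1,
      "noise_sd_pA": 10,
      "cap_amp_pA": 500,
      "cap_tau_ms": 0.5,
      "midpoint_sd": 0,
      "conductance_cv": 0,
      "delta": 0,
      "anchors": {}
    }
  }
}
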