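{
  "format": "mrspipe.pipe",
  "name": "mega",
  "nodes": [
    {
      "node_id": "coil_combination",
      "node_type": "coil_combination",
      "params": {
        "method": "adaptive"
      },
      "upstream": []
    },
    {
      "node_id": "frequency_phase_alignment",
      "node_type": "frequency_phase_alignment",
      "params": {
        "ppm_max": 3.6,
        "ppm_min": 1.6
      },
      "upstream": [
        "coil_combination"
      ]
    },
    {
      "node_id": "eddy_current_correction",
      "node_type": "eddy_current_correction",
      "params": [],
      "upstream": [
        "frequency_phase_alignment"
      ]
    },
    {
      "node_id": "bad_average_removal",
      "node_type": "bad_average_removal",
      "params": [],
      "upstream": [
        "eddy_current_correction"
      ]
    },
    {
      "node_id": "averaging",
      "node_type": "averaging",
      "params": [],
      "upstream": [
        "bad_average_removal"
      ]
    },
    {
      "node_id": "manual_adjustment",
      "node_type": "manual_adjustment",
      "params": [],
      "upstream": [
        "averaging"
      ]
    }
  ],
  "schema_version": 1,
  "version": "1"
}
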