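{
  "format": "mrspipe.pipe",
  "name": "fmrs",
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
      "node_id": "blocked_averaging",
      "node_type": "blocked_averaging",
      "params": {
        "avgs_per_block": 1,
        "meas_per_block": 16,
        "n_block_types": 2
      },
      "upstream": [
        "eddy_current_correction"
      ]
    }
  ],
  "schema_version": 1,
  "version": "1"
}
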