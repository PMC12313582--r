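{
  "format": "mrspipe.pipe",
  "name": "p31_svs",
  "nodes": [
    {
      "node_id": "frequency_phase_alignment",
      "node_type": "frequency_phase_alignment",
      "params": [],
      "upstream": []
    },
    {
      "node_id": "averaging",
      "node_type": "averaging",
      "params": [],
      "upstream": [
        "frequency_phase_alignment"
      ]
    },
    {
      "node_id": "entropy_phasing",
      "node_type": "entropy_phasing",
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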