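{
  "format": "mrspipe.pipe",
  "name": "p31_csi",
  "nodes": [
    {
      "node_id": "hanning_filter_3d",
      "node_type": "hanning_filter_3d",
      "params": [],
      "upstream": []
    },
    {
      "node_id": "apodization",
      "node_type": "apodization",
      "params": {
        "shape": "gaussian",
        "width_hz": 5
      },
      "upstream": [
        "hanning_filter_3d"
      ]
    }
  ],
  "schema_version": 1,
  "version": "1"
}
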