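{
  "graphs": [
    {
      "name": "oddball-calculate",
      "rate": 10,
      "nodes": [
        { "id": "src", "kind": "source", "params": {} },
        { "id": "ep", "kind": "epoch",
          "params": { "t_min": 0, "t_max": 0.8 } },
        { "id": "odd", "kind": "oddoneout",
          "params": { "class_ids": [1, 2, 3, 4],
                      "mode": "avg-then-cov" } }
      ],
      "edges": [
        { "source": "src:out", "target": "ep:in" },
        { "source": "src:markers", "target": "ep:markers" },
        { "source": "ep:out", "target": "odd:in" }
      ]
    }
  ],
  "session": {
    "app": "oddball",
    "instruction_dur": 10,
    "rest_dur": 5,
    "block_durs": [35, 35],
    "stim_rate": 3,
    "policy": "random"
  },
  "synth": {
    "fs": 256,
    "n_channels": 8,
    "line_freq": 50,
    "line_amp": 0.2,
    "erp_amp": 1,
    "hw_latency": 0.03,
    "seed": 1
  }
}
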