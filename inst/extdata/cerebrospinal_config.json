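{
  "reference_nodes": ["scv", "ra"],
  "viscosity_cP": 3,
  "flow_inputs": [
    {
      "node": "brain",
      "ml_s": 11.7,
      "label": "Q_c"
    },
    {
      "node": "qc1",
      "ml_s": 0.3,
      "label": "Q_v1"
    },
    {
      "node": "qc2",
      "ml_s": 0.3,
      "label": "Q_v2"
    },
    {
      "node": "qc3",
      "ml_s": 0.3,
      "label": "Q_v3"
    },
    {
      "node": "qc4",
      "ml_s": 0.3,
      "label": "Q_v4"
    },
    {
      "node": "qc5",
      "ml_s": 0.3,
      "label": "Q_v5"
    },
    {
      "node": "qc6",
      "ml_s": 0.3,
      "label": "Q_v6"
    },
    {
      "node": "qc7",
      "ml_s": 0.3,
      "label": "Q_v7"
    },
    {
      "node": "qt1",
      "ml_s": 0.4,
      "label": "Q_v8"
    },
    {
      "node": "qt2",
      "ml_s": 0.4,
      "label": "Q_v9"
    },
    {
      "node": "qt3",
      "ml_s": 0.4,
      "label": "Q_v10"
    },
    {
      "node": "qt4",
      "ml_s": 0.4,
      "label": "Q_v11"
    },
    {
      "node": "qt5",
      "ml_s": 0.4,
      "label": "Q_v12"
    },
    {
      "node": "qt6",
      "ml_s": 0.4,
      "label": "Q_v13"
    },
    {
      "node": "qt7",
      "ml_s": 0.4,
      "label": "Q_v14"
    },
    {
      "node": "qt8",
      "ml_s": 0.4,
      "label": "Q_v15"
    },
    {
      "node": "qt9",
      "ml_s": 0.4,
      "label": "Q_v16"
    },
    {
      "node": "qt10",
      "ml_s": 0.4,
      "label": "Q_v17"
    },
    {
      "node": "qt11",
      "ml_s": 0.4,
      "label": "Q_v18"
    },
    {
      "node": "qt12",
      "ml_s": 0.4,
      "label": "Q_v19"
    },
    {
      "node": "ql1",
      "ml_s": 0.5,
      "label": "Q_v20"
    },
    {
      "node": "ql2",
      "ml_s": 0.5,
      "label": "Q_v21"
    },
    {
      "node": "fem",
      "ml_s": 10,
      "label": "Q_f"
    }
  ]
}
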