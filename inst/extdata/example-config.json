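{
  "model": {
    "r1": 2,
    "r2": 2.5,
    "b": 10,
    "c": 0.001,
    "v": 1,
    "u": 0,
    "c_R": 0,
    "dt": 0.01,
    "L": 128,
    "allowed_a": [0, 50, 110],
    "active_a": [0, 110],
    "mutate_production": true,
    "mutate_resistance": false,
    "seed": 1
  },
  "experiment": "run",
  "composition": {
    "P110": 0.05,
    "N": 0.05,
    "S": 0.05
  },
  "stages": [
    {
      "time": 500,
      "set": {
        "u": 1e-4,
        "active_a": [0, 50, 110]
      }
    }
  ],
  "output_dir": "spatabx-out",
  "seed": 1
}
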