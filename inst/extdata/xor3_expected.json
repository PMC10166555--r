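{
  "name": "xor3",
  "vars": ["x", "y", "z"],
  "outputs": [0, 1, 1, 0, 1, 0, 0, 1],
  "polynomial": "x + y + z - 2*x*y - 2*x*z - 2*y*z + 4*x*y*z",
  "seed": 1,
  "evaluations": [
    {
      "assignment": {
        "x": 0.1849,
        "y": 0.7024,
        "z": 0.5733
      },
      "value": 0.481300806432
    },
    {
      "assignment": {
        "x": 0.1681,
        "y": 0.9438,
        "z": 0.9435
      },
      "value": 0.23869473172
    },
    {
      "assignment": {
        "x": 0.1292,
        "y": 0.8334,
        "z": 0.468
      },
      "value": 0.51582396416
    }
  ]
}
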