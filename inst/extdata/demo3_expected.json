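{
  "name": "demo3",
  "vars": ["x1", "x2", "x3"],
  "outputs": [0, 1, 0, 1, 0, 1, 1, 1],
  "polynomial": "x3 + x1*x2 - x1*x2*x3",
  "seed": 1,
  "evaluations": [
    {
      "assignment": {
        "x1": 0.1849,
        "x2": 0.7024,
        "x3": 0.5733
      },
      "value": 0.628717133392
    },
    {
      "assignment": {
        "x1": 0.1681,
        "x2": 0.9438,
        "x3": 0.9435
      },
      "value": 0.95246388207
    },
    {
      "assignment": {
        "x1": 0.1292,
        "x2": 0.8334,
        "x3": 0.468
      },
      "value": 0.52528324896
    }
  ]
}
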