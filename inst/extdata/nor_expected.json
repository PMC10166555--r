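{
  "name": "nor",
  "vars": ["a", "b"],
  "outputs": [1, 0, 0, 0],
  "polynomial": "1 - a - b + a*b",
  "seed": 1,
  "evaluations": [
    {
      "assignment": {
        "a": 0.1849,
        "b": 0.7024
      },
      "value": 0.24257376
    },
    {
      "assignment": {
        "a": 0.5733,
        "b": 0.1681
      },
      "value": 0.35497173
    },
    {
      "assignment": {
        "a": 0.9438,
        "b": 0.9435
      },
      "value": 0.0031753
    }
  ]
}
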