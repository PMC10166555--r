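{
  "name": "and",
  "vars": ["a", "b"],
  "outputs": [0, 0, 0, 1],
  "polynomial": "a*b",
  "seed": 1,
  "evaluations": [
    {
      "assignment": {
        "a": 0.1849,
        "b": 0.7024
      },
      "value": 0.12987376
    },
    {
      "assignment": {
        "a": 0.5733,
        "b": 0.1681
      },
      "value": 0.09637173
    },
    {
      "assignment": {
        "a": 0.9438,
        "b": 0.9435
      },
      "value": 0.8904753
    }
  ]
}
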