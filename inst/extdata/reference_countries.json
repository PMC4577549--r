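{
  "comment": "Reference-country assignments are data, not code.",
  "retrospective": {
    "Spain": ["Portugal"],
    "Hungary": ["East Germany", "West Germany"],
    "Russia": ["Belarus"]
  },
  "prospective": {
    "Spain": [],
    "Hungary": ["East Germany", "West Germany"],
    "Russia": ["Czech Republic", "Poland", "Hungary"]
  }
}
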