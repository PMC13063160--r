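{
  "3": {
    "scheme": 3,
    "rows": [
      {"grade": 1, "lo": 54, "hi": 101},
      {"grade": 2, "lo": 101, "hi": 129},
      {"grade": 3, "lo": 129, "hi": 162}
    ]
  },
  "5": {
    "scheme": 5,
    "rows": [
      {"grade": 1, "lo": 54, "hi": 85},
      {"grade": 2, "lo": 85, "hi": 101},
      {"grade": 3, "lo": 101, "hi": 129},
      {"grade": 4, "lo": 129, "hi": 150},
      {"grade": 5, "lo": 150, "hi": 162}
    ]
  },
  "6": {
    "scheme": 6,
    "rows": [
      {"grade": 1, "lo": 54, "hi": 66},
      {"grade": 2, "lo": 66, "hi": 85},
      {"grade": 3, "lo": 85, "hi": 101},
      {"grade": 4, "lo": 101, "hi": 129},
      {"grade": 5, "lo": 129, "hi": 150},
      {"grade": 6, "lo": 150, "hi": 162}
    ]
  }
}
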