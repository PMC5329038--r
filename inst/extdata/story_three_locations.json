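[
  {
    "subject": "Murat",
    "verb": "put",
    "object": "chocolate",
    "location": "drawer",
    "time_index": 1
  },
  {
    "subject": "Ayla",
    "verb": "put",
    "object": "chocolate",
    "location": "toy_box",
    "time_index": 2
  },
  {
    "subject": "Murat",
    "verb": "saw",
    "object": "Ayla",
    "location": "none",
    "time_index": 2
  },
  {
    "subject": "Ayla",
    "verb": "did-not-see",
    "object": "Murat",
    "location": "none",
    "time_index": 2
  },
  {
    "subject": "mother",
    "verb": "put",
    "object": "chocolate",
    "location": "tv_stand",
    "time_index": 3
  }
]
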