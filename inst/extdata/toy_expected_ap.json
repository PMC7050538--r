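{
  "_comment": "Hand-enumerated expected AP fingerprints (max_distance 7) for the toy_molecules() fixtures.",
  "methane": {},
  "propane": {
    "AP|C(1,0)|1|C(2,0)": 2,
    "AP|C(1,0)|2|C(1,0)": 1
  },
  "ethanol": {
    "AP|C(1,0)|1|C(2,0)": 1,
    "AP|C(2,0)|1|O(1,0)": 1,
    "AP|C(1,0)|2|O(1,0)": 1
  },
  "benzene": {
    "AP|C(2,2)|1|C(2,2)": 6,
    "AP|C(2,2)|2|C(2,2)": 6,
    "AP|C(2,2)|3|C(2,2)": 3
  },
  "two_fragments": {
    "AP|C(1,0)|1|C(1,0)": 1
  }
}
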