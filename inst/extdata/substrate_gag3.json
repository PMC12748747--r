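{
  "name": "gag3",
  "top_seq": "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTCAGCATATCTCGTGAACCCCCTGCACGCCCTGAG",
  "bottom_seq": "AGGGCGTGCAGGGGGTTCACGAGATATATCAGGGCCGAGTGCAAGATTCTACTTCCGGAGTTACACATGGAGTTTTGAG",
  "head": {
    "polarity": "three_prime_overhang",
    "overhang_seq": "GAG",
    "label": "head"
  },
  "tail": {
    "polarity": "three_prime_overhang",
    "overhang_seq": "GAG",
    "label": "tail"
  },
  "strand_id": {
    "start": 44,
    "top_variant": "TCAGC",
    "bottom_variant": "ATCAG"
  }
}
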