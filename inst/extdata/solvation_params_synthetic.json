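{
  "comment": "Synthetic reference parameter table (not literature values): ground truth for the packaged generators, calibrated so 69-residue synthetic bundles score in the -55 to -20 kcal/mol range typical of soluble helical miniproteins.",
  "sigma": 3.5,
  "types": {
    "C.ali": {"S": 0.0008,  "Omax": 350, "V": 18},
    "C.aro": {"S": 0.0006,  "Omax": 340, "V": 16},
    "C.car": {"S": 0.0004,  "Omax": 350, "V": 10},
    "N.ami": {"S": -0.0022, "Omax": 350, "V": 12},
    "N.chg": {"S": -0.0065, "Omax": 340, "V": 13},
    "O.car": {"S": -0.0030, "Omax": 340, "V": 11},
    "O.hyd": {"S": -0.0037, "Omax": 340, "V": 12},
    "O.chg": {"S": -0.0094, "Omax": 330, "V": 13},
    "S":     {"S": 0.0004,  "Omax": 340, "V": 20},
    "H.pol": {"S": -0.0019, "Omax": 150, "V": 4},
    "H.non": {"S": 0.0002,  "Omax": 170, "V": 5}
  }
}
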