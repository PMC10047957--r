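{
  "RHEE": "CA", "LHEE": "CA", "HEE": "CA", "HEEL": "CA", "RCAL": "CA", "LCAL": "CA",
  "RSTL": "MCA", "LSTL": "MCA", "STAL": "MCA",
  "RLCA": "LCA", "LLCA": "LCA", "PCAL": "LCA",
  "RTOE": "TOE", "LTOE": "TOE", "RD5M": "TOE", "LD5M": "TOE",
  "RP1M": "MTH", "LP1M": "MTH", "RMT2": "MTH", "LMT2": "MTH", "MET": "MTH",
  "RANK": "LMA", "LANK": "LMA", "RLMAL": "LMA", "LLMAL": "LMA",
  "RMMA": "MMA", "LMMA": "MMA", "RMMAL": "MMA", "LMMAL": "MMA",
  "RKNE": "KNE", "LKNE": "KNE", "RLEK": "KNE", "LLEK": "KNE",
  "RTIB": "TIB", "LTIB": "TIB", "RSHA": "TIB", "LSHA": "TIB",
  "RHLX": "HLX", "LHLX": "HLX"
}
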