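{
  "subcommand": "track",
  "options": {
    "out": "x"
  },
  "input_md5": {},
  "config": {
    "lowFraction": 0.3,
    "highFraction": 0.5,
    "growthFraction": 0.075,
    "thresholdBump": 0.2,
    "minArea": 10,
    "maxAreaFactor": 1.3333,
    "terminalGrowthFraction": 0.5,
    "windowPad": 10,
    "phasePenaltyWeight": 0.25,
    "scorePercentile": 90,
    "seedOverlapMin": 0.4,
    "noncellMax": 0.3333
  },
  "package_version": "0.1.0",
  "timestamp": "2026-09-22T11:59:53+0000"
}
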