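{
  "id": "Tracking_2D",
  "field": {
    "algo": "hexgrid",
    "bgcThreshold": 10,
    "ctrDwellFactor": 1,
    "damping": 0,
    "headstart": 1,
    "loclimit": 110,
    "stickiness": 4,
    "fieldGeoFactor": 1
  },
  "deadtimes": { "fast_ms": 0.011, "estimator_ms": 0.015, "slow_ms": 0.04 },
  "itr": [
    {
      "pattern": "triangle",
      "L": 284,
      "patDwellTime": 0.1,
      "patRepeat": 1,
      "pwrFactor": 1,
      "phtLimit": 40,
      "ccrLimit": -1,
      "maxOffTime": 3,
      "wavelength": 640,
      "estimator": "iter_lsq"
    },
    {
      "pattern": "triangle",
      "L": 150,
      "patDwellTime": 0.2,
      "patRepeat": 1,
      "pwrFactor": 1,
      "phtLimit": 100,
      "ccrLimit": -1,
      "maxOffTime": 3,
      "wavelength": 640,
      "estimator": "iter_lsq"
    },
    {
      "pattern": "triangle",
      "L": 75,
      "patDwellTime": 0.3,
      "patRepeat": 3,
      "pwrFactor": 1,
      "phtLimit": 500,
      "ccrLimit": 0.9,
      "maxOffTime": 3,
      "wavelength": 640,
      "estimator": "iter_lsq"
    }
  ]
}
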