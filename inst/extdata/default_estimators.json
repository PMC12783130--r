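{
  "default": "iter_lsq",
  "itr": ["lsq_donut", "iter_lsq", "iter_lsq"]
}
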