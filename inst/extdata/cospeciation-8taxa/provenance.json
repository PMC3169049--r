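{
  "scenario": {
    "n_hosts": 8,
    "yule_rate": 1,
    "n_switches": 0,
    "virus_rate_scale": 0.3,
    "seed": 1001
  },
  "model": {
    "exch": [1.5, 4, 0.9, 1.1, 4.5, 1],
    "base_freq": [0.3, 0.2, 0.2, 0.3],
    "gamma_shape": 0.5,
    "p_inv": 0.1,
    "k": 4
  },
  "L": 2000
}
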