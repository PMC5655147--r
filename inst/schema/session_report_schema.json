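{
  "title": "lfpcoupling session report",
  "required_fields": {
    "id": {},
    "seed": {},
    "duration_s": {},
    "fs": {},
    "architecture": {
      "total_nrem_s": {},
      "mean_nrem_epoch_s": {},
      "n_nrem_epochs": {},
      "total_rem_s": {},
      "total_wake_s": {}
    },
    "band_power": {
      "CA1_LFP": {
        "delta": {},
        "theta": {},
        "alpha": {},
        "beta": {},
        "gamma": {}
      },
      "ACC_LFP": {
        "delta": {},
        "theta": {},
        "alpha": {},
        "beta": {},
        "gamma": {}
      }
    },
    "params": {},
    "hypnogram": {}
  }
}
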