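{
  "baseline_threshold": 1,
  "suppression_trailing": 0.49,
  "suppression_leading": 0.54,
  "prediction_amplitude": 0.52,
  "support_semisat": 15,
  "projection_constant": 25,
  "temporal_semisat": 122,
  "interocular_transfer": 0.5,
  "transfer_suppression": false,
  "psychometric_slope": 10,
  "lapse_rate": 0,
  "rng_seed": 1
}
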