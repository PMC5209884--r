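{
  "id": "g_diabetic",
  "seed": 1,
  "subgroups": [
    {
      "name": "diabetic",
      "size": 2040,
      "diseased_fraction": 0.30,
      "p_index_pos_given_diseased": 0.838,
      "p_index_pos_given_healthy": 0.05,
      "p_ref_pos_given_diseased": 0.98,
      "p_ref_pos_given_healthy": 0.02
    }
  ]
}
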