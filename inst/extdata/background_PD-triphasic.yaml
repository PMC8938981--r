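rate:
  D1-SPN: 2412.963909348651669
  D2-SPN: 2105.824383857515841
  FSI: 2760.83723211315737
  STN: 832.46732597240657
  GPe-TA: 165.650233926789156
  GPe-TI: 0.484002582470509
  SNr: 147.578905599999928
weight:
  D1-SPN: 3.0
  D2-SPN: 3.0
  FSI: 3.0
  STN: 3.0
  GPe-TA: 3.0
  GPe-TI: 3.0
  SNr: 3.0
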