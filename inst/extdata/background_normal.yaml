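rate:
  D1-SPN: 1933.333333333333258
  D2-SPN: 2166.666666666666515
  FSI: 2105.666666666666515
  STN: 670.471741406824208
  GPe-TA: 76.190476190476147
  GPe-TI: 14.0
  SNr: 1430.0
weight:
  D1-SPN: 3.0
  D2-SPN: 3.0
  FSI: 3.0
  STN: 3.0
  GPe-TA: 3.0
  GPe-TI: 3.0
  SNr: 3.0
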