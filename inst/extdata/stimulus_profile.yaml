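# Frozen transient cortical stimulus, fitted once in the healthy condition
# against the early-excitation latency/duration and early-inhibition latency
# anchors of the nigral response, then reused unchanged for every condition
# and experiment.
pulse_rate: 3000.0
pulse_dur: 4.0
supp_frac: 0.3
supp_dur: 20.0
plateau_rate: 0.0
plateau_dur: 0.0
shape: rect
weight:
  D1-SPN: 0.9
  D2-SPN: 1.5
  STN: 2.2
delay:
  D1-SPN: 1.0
  D2-SPN: 1.0
  STN: 2.0
targets:
- D1-SPN
- D2-SPN
- STN
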