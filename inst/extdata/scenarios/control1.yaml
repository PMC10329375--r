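# Mechanical-bench control: linear compliance, no airway closure.
name: control1
description: linear compliance 40 mL/cmH2O, Rrs 10, no airway closure
system:
  rrs: 10
  compliance:
    linear: 40
circuit:
  ccirc: 2
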