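# Mechanical-bench control: bilinear compliance (lower inflection point),
# no airway closure.
name: control2
description: bilinear compliance 20/40 mL/cmH2O with LIP 10 cmH2O, Rrs 10, no airway closure
system:
  rrs: 10
  compliance:
    bilinear:
      c_below: 20
      c_above: 40
      lip: 10
circuit:
  ccirc: 2
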