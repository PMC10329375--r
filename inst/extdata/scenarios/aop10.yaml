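# Mechanical-bench model: passive patient with airway closure at 10 cmH2O.
name: aop10
description: linear compliance 40 mL/cmH2O, Rrs 10, airway opening pressure 10 cmH2O
system:
  rrs: 10
  compliance:
    linear: 40
  aop: 10
circuit:
  ccirc: 2
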