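stock: BDSC_647
source: Bloomington
genotype: ey[1] / ey[1]
copy_number: 2
trisomic: no
assumption: deficiency gene content is modeled as a private essential region locus
  (plus ey for Df(4)ED6380), matching the complementation behavior of the published
  crosses, not mapped breakpoints
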