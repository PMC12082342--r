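stock: BDSC_9549
source: Bloomington
genotype: w[1118] ; P{ActGFP}unc-13[GJ] / In(4)ci[D], ci[D], pan[ciD]
copy_number: 2
trisomic: no
assumption: deficiency gene content is modeled as a private essential region locus
  (plus ey for Df(4)ED6380), matching the complementation behavior of the published
  crosses, not mapped breakpoints
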