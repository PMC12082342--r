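stock: Kyoto_150531
source: Kyoto
genotype: w[1118] ; Df(4)ED6382, P{3'.RS5+3.3'}ED6382 / P{ActGFP}unc-13[GJ] / P{ActGFP}unc-13[GJ]
copy_number: 3
trisomic: yes
assumption: deficiency gene content is modeled as a private essential region locus
  (plus ey for Df(4)ED6380), matching the complementation behavior of the published
  crosses, not mapped breakpoints
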