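loci:
- name: RpS3A
  essential: yes
  haploinsufficient: yes
  recessive_phenotype: ~
  dominant_phenotype: Minute
- name: l(4)102EFf
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: ey
  essential: no
  haploinsufficient: no
  recessive_phenotype: eyeless
  dominant_phenotype: ~
- name: ci
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: pan
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: unc-13
  essential: no
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: Crk
  essential: no
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: Gat
  essential: no
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: In(4)ciD-lethal
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: RS5-element
  essential: no
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: ED6369-region
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: ED6380-region
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: ED6382-region
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
- name: ED6384-region
  essential: yes
  haploinsufficient: no
  recessive_phenotype: ~
  dominant_phenotype: ~
alleles:
  RpS3A[57g]:
    locus: RpS3A
    functional: no
    marker: ~
  ey[1]:
    locus: ey
    functional: no
    marker: ~
  l(4)102EFf[1]:
    locus: l(4)102EFf
    functional: no
    marker: ~
  In(4)ci[D]:
    locus: In(4)ciD-lethal
    functional: no
    marker: ~
  ci[D]:
    locus: ci
    functional: yes
    marker: ci-D
  pan[ciD]:
    locus: pan
    functional: yes
    marker: ~
  P{ActGFP}unc-13[GJ]:
    locus: unc-13
    functional: no
    marker: GFP
  TI{TI}Crk[dsRed]:
    locus: Crk
    functional: yes
    marker: dsRed
  TI{GMR-HMS04515}Gat[eya]:
    locus: Gat
    functional: yes
    marker: ~
  P{3'.RS5+3.3'}ED6369:
    locus: RS5-element
    functional: yes
    marker: ~
  P{3'.RS5+3.3'}ED6380:
    locus: RS5-element
    functional: yes
    marker: ~
  P{3'.RS5+3.3'}ED6382:
    locus: RS5-element
    functional: yes
    marker: ~
  P{3'.RS5+3.3'}ED6384:
    locus: RS5-element
    functional: yes
    marker: ~
deficiencies:
  Df(4)ED6369:
  - ED6369-region
  Df(4)ED6380:
  - ED6380-region
  - ey
  Df(4)ED6382:
  - ED6382-region
  Df(4)ED6384:
  - ED6384-region
copy_class_viability:
  nullosomic: 0.0
  monosomic: 0.5
  disomic: 1.0
  trisomic: 1.0
  tetrasomic: 0.0
phenotype_viability:
  Minute: 0.7
monosomic_label: haplo-4
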