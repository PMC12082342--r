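# triplo4

Exact transmission genetics for fourth-chromosome trisomy in *Drosophila
melanogaster* stocks.

## The problem

Flies carrying an extra fourth chromosome (triplo-4) are viable and look
essentially normal, and nondisjunction creates the gametes that found them
in roughly 1 of every 500 meioses — so laboratory stocks quietly become
trisomic, especially deletion stocks in which an extra normal homolog masks
the haploinsufficiency of the deficiency chromosome. An unnoticed extra
chromosome 4 then distorts segregation ratios, contaminates newly built
stocks, and can make mutations appear to complement when they do not.

triplo4 is for fly geneticists and stock keepers who need to quantify,
diagnose, and design around this: it computes exact gamete and
progeny-class distributions, simulates stocks forward in time, and fits
segregation-distortion parameters from counts.

## The model in brief

At meiosis I the three homologs of a trisomic form a paired bivalent plus
an unpaired univalent in three configurations with weights
$p = (p_1, p_2, p_3)$; the univalent joins the pole of the first bivalent
partner with probability $u_i$. Six segregation patterns produce six gamete
classes (each from exactly two patterns). Under random behavior
($p_i = 1/3$, $u = 1/2$) the classes occur at $1/6$ each, and for **any**
$p, u$ half the gametes are disomic — the half-disomic law. Disomic parents
nondisjoin at rate $d$ (default $1/500$), split evenly between diplo and
nullo gametes.

A rules engine maps karyotypes to phenotypes and viabilities: essential
loci (lethal at zero functional copies), haploinsufficient loci (*Minute*
at exactly one copy — the `RpS3A[57g]` tester logic), recessive and
dominant markers, deficiencies, and balancer lethality. The cross engine
takes the outer product of two gamete distributions and reports exact
progeny classes with raw and viability-adjusted frequencies; because a
trisomic parent sends two chromosomes to half its gametes, its
tester-bearing progeny include **non-Minute** classes that a disomic parent
cannot produce — the diagnostic signature. With equal viabilities that
signature has total frequency $q = 1/4$, so scoring $n$ progeny detects
trisomy with power $1 - (3/4)^n$.

## Worked example: is this stock trisomic?

Cross a fly from the suspect stock (here the trisomic
`Df(4)ED6382/P{ActGFP}unc-13[GJ]/P{ActGFP}unc-13[GJ]` deletion stock) to
the `RpS3A[57g]`/balancer tester and enumerate the progeny:

```r
library(triplo4)
rules   <- default_rules()
m0      <- segregation_model(nondisjunction_rate = 0)
suspect <- stock_karyotype("Kyoto_150531", rules)
tester  <- stock_karyotype("BDSC_1229", rules)
res <- cross(suspect, tester, m0, rules)
res
#>  class                                                                 raw    adjusted phenotypes note
#>  Df(4)ED6382, ... / In(4)ci[D], ci[D], pan[ciD] / P{ActGFP}unc-13[GJ]  0.1667 0.1802   ci-D;GFP
#>  Df(4)ED6382, ... / P{ActGFP}unc-13[GJ] / RpS3A[57g]                   0.1667 0.1802   GFP        diagnostic
#>  In(4)ci[D], ci[D], pan[ciD] / P{ActGFP}unc-13[GJ]                     0.1667 0.1802   ci-D;GFP
#>  P{ActGFP}unc-13[GJ] / RpS3A[57g]                                      0.1667 0.1261   GFP;Minute
#>  Df(4)ED6382, ... / In(4)ci[D], ci[D], pan[ciD]                        0.0833 0.0901   ci-D
#>  Df(4)ED6382, ... / RpS3A[57g]                                         0.0833 0.0631   Minute
#>  In(4)ci[D], ci[D], pan[ciD] / P{ActGFP}unc-13[GJ] / P{ActGFP}unc-13[GJ] 0.0833 0.0901 ci-D;GFP
#>  P{ActGFP}unc-13[GJ] / P{ActGFP}unc-13[GJ] / RpS3A[57g]                0.0833 0.0901   GFP        diagnostic
```

The two `diagnostic` rows are tester-bearing yet non-Minute: they inherited
two fourth chromosomes from the suspect parent, which is therefore
trisomic.

```r
detect_trisomy_signature(res)$detected
#> TRUE
select_disomic_founders(res, "Df(4)ED6382, P{3'.RS5+3.3'}ED6382")[, c("class", "frequency_adjusted")]
#>                                            class frequency_adjusted
#> 1 Df(4)ED6382, P{3'.RS5+3.3'}ED6382 / RpS3A[57g]         0.06306306
trisomy_detection_power(10, suspect, tester, m0, default_rules(minute_viability = 1))
#> 0.9436865
```

The single founder class — disomic, Minute, deletion-bearing, about 6% of
surviving progeny under the default Minute viability — is the fly to cross
onward to balancer females to establish a clean disomic stock. Scoring ten
progeny already detects a trisomic parent with ~94% probability.

Other entry points: `simulate_stock()` / `trisomy_invasion_probability()`
(forward simulation of a closed stock under nondisjunction and selection),
`fit_segregation_params()` (multinomial MLE of pairing bias from progeny
counts), `blind_scheme_success_probability()` (why blind founder-picking
fails under preferential segregation), `generate_fixtures()` and
`parse_genotype()` (the genotype grammar and the ten bundled stock-center
stock definitions in `inst/extdata/`). A thin command-line wrapper with
`cross`, `simulate-stock`, `power`, `fit-segregation`, and `make-fixtures`
subcommands is installed at `exec/triplo4`. See the vignette
`vignettes/trisomy4-model.Rmd` for the full model description.

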