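---
title: "Modeling fourth-chromosome trisomy in Drosophila stocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fourth-chromosome trisomy in Drosophila stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplo4)
```

## The problem

The fourth chromosome of *Drosophila melanogaster* is tiny, achiasmate, and
unusually tolerant of dosage imbalance: flies carrying three copies
(triplo-4) are viable and nearly indistinguishable from normal disomic
flies. Because spontaneous nondisjunction creates diplo-4 gametes at an
appreciable rate, and because an extra normal fourth chromosome can mask the
haploinsufficiency of a deletion-bearing homolog, laboratory stocks drift
toward trisomy without anyone noticing — and extra fourth chromosomes then
ride silently through crossing schemes, confound complementation tests, and
contaminate newly built stocks.

triplo4 provides an exact calculus for this situation: what gametes a
trisomic parent makes, what progeny any cross produces, how trisomy spreads
in a closed stock, and how to design crosses that diagnose trisomy and
recover disomic lines.

## The segregation model

At meiosis I the three homologs of a trisomic form one paired bivalent plus
one unpaired univalent, in three possible configurations. The bivalent
partners segregate from each other; the univalent joins either pole. Six
segregation patterns therefore produce six gamete classes (three monosomic,
three disomic), each class arising from exactly two patterns.

For label-sorted copies (1, 2, 3), configuration $i$ (bivalent $X$–$Y$,
univalent $Z$) has pairing weight $p_i$ ($\sum p_i = 1$) and univalent bias
$u_i$, the probability that $Z$ segregates with $X$, the first (label-sorted)
bivalent partner. The gamete distribution is

$$
\Pr(\{X,Z\}) \mathrel{+}= \tfrac{1}{2} p_i u_i,\quad
\Pr(\{Y\}) \mathrel{+}= \tfrac{1}{2} p_i u_i,\quad
\Pr(\{Y,Z\}) \mathrel{+}= \tfrac{1}{2} p_i (1-u_i),\quad
\Pr(\{X\}) \mathrel{+}= \tfrac{1}{2} p_i (1-u_i).
$$

Two consequences matter in practice:

* **Uniform ratio.** With $p = (1/3, 1/3, 1/3)$ and $u = 1/2$ (random
  pairing and segregation) all six classes occur at $1/6$.
* **Half-disomic law.** For *any* $p$ and $u$, every pattern sends one
  disomic and one monosomic product to opposite poles, so exactly half the
  gametes are disomic. Preferential (Sturtevant-style) pairing reshuffles
  mass *within* the monosomic and disomic halves but cannot change the
  halves themselves. Only gamete-level transmission weights (meiotic
  drive / gamete competition), deliberately kept as a separate parameter,
  can break this law; zygotic viability lives in the rules engine, on the
  other side of the module boundary.

Disomic parents transmit each homolog to half their gametes except for
nondisjunction at rate $d$ (default $d = 0.002$, one affected meiosis in
500), split evenly between diplo and nullo gametes — the even split is the
standard null in the absence of any measured asymmetry. Monosomic parents
are modeled with the single chromosome as a free univalent (half the
gametes carry it, half are nullosomic); this case exists mostly so the
nullo-gamete path is exercisable. Trisomic meiosis has no additional
nondisjunction channel: the six-pattern model already exhausts the
bivalent+univalent geometry. Trivalent or triple-univalent configurations
are not modeled — a known limitation, acceptable for a chromosome this
small.

## Genotype → phenotype rules

A karyotype is a multiset of 0–4 labelled chromosome-4 copies; each copy
carries allele states at named loci (unlisted loci are implicitly
functional) or deletes loci outright. The rules engine counts functional
copies per locus:

* essential locus at 0 copies → lethal;
* haploinsufficient locus at exactly 1 copy → its dominant label
  (*Minute*), the core of the tester logic: `RpS3A[57g]` heterozygotes over
  a single normal homolog are Minute, but over two homologs are not;
* non-essential locus at 0 copies → recessive label (*eyeless*);
* dominant markers (GFP, `ci[D]`) emitted whenever present.

Viability is multiplicative: a copy-number-class base weight (nullosomic 0,
monosomic 0.5, disomic 1, trisomic 1, tetrasomic 0) times one weight per
phenotype label. The biological facts embedded in the defaults: triplo-4
is fully viable (weight 1); haplo-4 flies are viable but Minute-like
(base 0.5, and they also pick up the Minute label since every
haploinsufficient locus sits at one copy); nullosomic and tetrasomic
zygotes are treated as lethal — the diagnostic logic never depends on
these two classes, and both weights are overridable. The Minute viability
penalty is real but unquantified in the literature we model; the default
0.7 is a documented placeholder, and every quantitative claim the package
tests is either independent of it or parameterized over it.

The bundled deficiencies (`Df(4)ED6369/80/82/84`) are modeled by a private
essential "region" locus each — enough to make them homozygous lethal and
viable over a normal homolog — plus deletion of *ey* for `Df(4)ED6380`
(whose heterozygotes with `ey[1]` are eyeless). Their true gene content is
not modeled; the fixture files carry this assumption explicitly.

## The cross engine and the tester diagnosis

`cross()` takes the outer product of two gamete distributions, merges
zygotes with identical unordered copy multisets (phenotype logic is
origin-free), classifies each class, and reports both raw and
viability-renormalized frequencies; lethal classes stay in the table at
adjusted frequency 0 so balanced-lethal structure is visible.

The diagnosis: cross a suspect fly to the `RpS3A[57g]` tester. Every
tester-bearing offspring of a *disomic* parent received exactly one other
chromosome 4 and is Minute. A *trisomic* parent sends disomic gametes to
half its offspring, producing tester-bearing, *non-Minute* progeny —
`detect_trisomy_signature()` returns exactly those classes. With equal
viabilities their summed frequency is $q = 1/4$ (half-disomic law × the
tester's 1/2), so scoring $n$ progeny detects trisomy with power
$1 - (3/4)^n$ — about 94% at $n = 10$. The same table yields the disomic,
Minute, target-bearing founder classes (`select_disomic_founders()`) used
to establish a clean disomic stock, and
`blind_scheme_success_probability()` quantifies why the traditional blind
approach fails when the deletion chromosome preferentially co-segregates
with its partners: the disomic fraction among target-bearing candidates
drops toward zero and $1-(1-p)^k$ collapses with it.

## Stock simulation

`simulate_stock()` advances a closed population in non-overlapping
generations at fixed census size $N$ with an enforced even sex ratio
(stratified resampling), random mating, meiosis through the segregation
model, and viability selection on zygotes. Each offspring draws parents
independently from the fecundity-weighted parental frequencies, so the
per-generation offspring distribution is computed exactly over karyotype
classes and then multinomially resampled — algebraically identical to
per-individual Wright–Fisher sampling with viability rejection, but fast
enough for hundreds of generations and replicates. Extinction (no viable
offspring possible) is a flagged terminal state, not an error.

One modeling consequence worth stating: with tetrasomic zygotes lethal,
"viability-neutral" trisomy is not actually neutral. Trisomic × trisomic
matings lose their tetrasomic quarter, giving the exact one-generation
expectation $E[f'] = f/(1 + f/2)$ for trisomic frequency $f$ — a slow
deterministic decline. The simulator is tested against this recursion, not
against flatness. Trisomy spreads when it confers an advantage, the
regime the deletion stocks realize: in a balanced-lethal `Df/l/l` stock
where `Df/l` disomics suffer a Minute-like haploinsufficiency (tested at
relative viability 0.8) that the extra chromosome masks, simulated trisomy
rises from 5% to a majority of the stock within ~40 generations at
$N = 100$.

Test problem sizes (census 20–200, 1–40 generations, 12–150 replicates)
were chosen as the smallest scales at which the drift and selection
signatures are statistically unambiguous under the fixed seeds used.

## Fitting segregation bias from counts

`fit_segregation_params()` maximizes the multinomial likelihood of observed
progeny-class counts over the pairing simplex (softmax reparameterization)
and optionally the univalent biases (logit), by BFGS from 10 seeded starts;
viabilities and the tester parent's segregation are held fixed. Because the
class probabilities are linear in the trisomic parent's six gamete
frequencies, the predictor is precomputed as a 6-column matrix and each
likelihood evaluation is a matrix-vector product.

Identifiability drives two design choices. First, biases default to fixed
$u = 1/2$: six observable gamete classes cannot support six free
parameters. Second, stocks whose trisomic parent carries duplicate homologs
(e.g. `Df/l/l`) make two pairing configurations label-identical, so only
$p_1 + p_2$ and $p_3$ are estimable; the fitter detects this as a flat
likelihood direction (near-singular Hessian) and says so rather than
reporting arbitrary splits. Boundary estimates (a pairing weight at 0 or 1,
as when monosomic-deletion gametes are entirely absent) are flagged and
warned. A grid-search oracle (`fit_segregation_grid`, step 0.05) ships for
independent verification, and parametric-bootstrap percentile intervals are
available opt-in. With three distinguishable homologs and 10,000 scored
progeny, pairing weights are recovered within ±0.05 (tested over 20
replicates; observed worst error ≈ 0.02).

## Numerical and interface choices

* Gamete-class and karyotype identity use label-sorted keys, so `A,B` ≡
  `B,A` and copies with equal labels are interchangeable — duplicate
  homologs merge correctly.
* Distributions validate to sum 1 within $10^{-12}$; zero-probability
  classes are dropped from gamete distributions (a $d=0$ disomic parent has
  exactly two gamete classes).
* All sampling goes through an internal seed guard that restores the
  caller's RNG state; the same seed reproduces a full simulation
  trajectory byte-for-byte.
* Genotype strings use an ASCII bracket grammar (`RpS3A[57g]`); superscript
  notation is normalized on input, and parse → format → parse is the
  identity. Unknown designators become inert markers with a warning rather
  than hard errors, so exploratory genotypes do not require editing the
  rule set first.
* Configs are YAML; count tables and outputs are TSV. The ten stock-center
  stocks used throughout the examples ship as validated YAML fixtures in
  `inst/extdata/`, regenerable with `generate_fixtures()`.

## What the synthetic data does and does not show

Simulated progeny counts are exact multinomial draws from the model's own
class distribution: they validate the estimator's correctness and
calibration, not the model's fit to real flies. Real test crosses add
brood structure, scoring error (Minute bristles are easier to call in
females), viability that varies with genetic background, and possible
transmission distortion downstream of meiosis — none of which the
generator emulates. Likewise the stock simulator's clean demography
(discrete generations, fixed N, even sex ratio) abstracts away vial
transfers and bottlenecks; its results are qualitative guides to how fast
trisomy can invade, not forecasts for a particular stock room.

## Known limitations

* No recombination (correct for chromosome 4), no trivalent pairing, no
  post-fertilization chromosome loss, no mitotic nondisjunction.
* Aneuploidy of the other chromosomes is out of scope; X-linked background
  markers are carried as inert labels only.
* The Minute viability/fecundity deficit and all selection coefficients
  are user parameters — the package deliberately ships no empirical claim
  about their magnitude.
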