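---
title: "Modelling two-locus gametophytic incompatibility with bdmgamete"
author: "bdmgamete authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-locus gametophytic incompatibility with bdmgamete}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmgamete)
```

## The model

Duplicate genes that lose function reciprocally in two diverging lineages
create a classic Bateson–Dobzhansky–Muller (BDM) incompatibility: a gamete
(or zygote) that inherits the non-functional copy at *both* loci has no
working gene at all.  When the gene product is needed by the haploid male
gametophyte, the incompatibility acts gametophytically — pollen grains
carrying the doubly-null haplotype abort, female gametes of the same
genotype are unaffected, and the result is transmission ratio distortion
without any loss of zygotes.

`bdmgamete` models this with three small pieces:

* **Gamete generation.**  A diploid parent produces haplotypes under a
  Markov crossover process: the transmitted strand is chosen with
  probability 1/2 at the first locus and switches between adjacent loci
  with their recombination fraction $r$.  Loci on different chromosomes
  have $r = 0.5$.  Unphased genotypes are accepted only when at most one
  heterozygous locus sits in each linkage group; otherwise the phase must
  be supplied explicitly, because silently guessing it would give wrong
  answers for linked loci.
* **Gametic selection.**  A selection model is a set of rules
  (haplotype pattern with wildcards, sex, penetrance).  A gamete matching
  a rule survives with probability $1 - \text{penetrance}$; the surviving
  distribution is renormalised, and the normalisation constant — the
  transmitted fraction — is the plant's expected pollen fertility when
  the sex is male.  The canonical rule here is "male gametes carrying
  B|A (donor allele at locus 1, recurrent allele at locus 2) are
  sterile" with penetrance 1.
* **Fusion.**  Offspring distributions are outer products of the two
  sex-specific gamete distributions, aggregated to unphased genotype
  classes in a fixed locus-major order (AA < AB < BB, first locus
  slowest), the row order of published two-locus segregation tables.

Selfing a plant heterozygous at both (unlinked) loci under the male
B|A-sterile rule yields genotype classes in the exact rational
proportions $(1,2,1,1,3,2,0,1,1)/12$ and pollen-fertility classes
50%, 75% and 100% in a 2:3:7 ratio:

```{r ratio}
sterile <- selection_model(selection_rule("B|A", "male"))
d <- offspring_distribution("AB|AB", "AB|AB", sterile)
round(d * 12)
fertility_class_distribution(d, sterile)
```

Because the offspring genotype distribution is symmetric in which sex
carries the selection, genotype counts alone can never attribute the
selected sex; the pollen-fertility phenotype breaks the tie.  This
asymmetry is a property the test suite asserts, not an accident.

## Model fitting

`bdm_fit()` scores candidate selection models against per-plant data by
the joint log-likelihood of (i) the multinomial genotype counts under
the candidate's expected distribution and (ii) each plant's fertile
grain count under a beta-binomial observation model centred on the
plant's model-implied fertility.  The default candidate set is the four
two-locus haplotypes crossed with male/female/both plus the neutral
model (13 candidates, all parameter-free, ranked by raw log-likelihood;
no information criterion is needed for an equal-complexity family).  A
candidate that assigns probability zero to an observed outcome scores
$-\infty$ and ranks last rather than erroring, so impossible models are
reported, not hidden.

## Transgene rescue and copy number

A hemizygous transgene insertion reaches half the gametes.  With $c$
independent unlinked insertions of a functional gene copy, a
sterile-haplotype pollen grain is rescued with probability
$q = 1 - (1/2)^c$.  For a single-locus semisterile selfer the T1 ratios
are 1:1:0 at $c = 0$, 2:3:1 at $c = 1$, and tend to Mendelian 1:2:1 as
$c \to \infty$, with the heterozygote frequency pinned at exactly 1/2
for every $c \ge 1$.  `estimate_copy_number()` profiles the multinomial
likelihood over integer $c$.

Two deliberate choices:

* **`marker_r = 0.005` by default.**  Genotypes are scored at a marker
  tightly linked to the rescued gene, not at the gene itself.  Giving
  the marker half a map unit of recombination keeps a small positive
  probability for the double-recessive class under the no-rescue model,
  so a control family of 45:48:1 is correctly estimated as $c = 0$ with
  the single double-recessive plant flagged as a putative marker–gene
  recombinant, instead of being forced to $c \ge 1$ by a structural
  zero.  Setting `marker_r = 0` recovers the idealised closed forms.
* **Boundary flagging.**  $\hat{c} = $ `max_c` is reported as
  "$\ge$ max_c": the likelihood differences between large copy numbers
  vanish, so the top of the profile is a one-sided statement.

A known identifiability limit, visible directly from the class
probabilities: adjacent copy numbers beyond 1 are nearly
indistinguishable at realistic family sizes (for $c = 2$ vs $c = 3$ the
expected AA/AB/BB frequencies are 0.286/0.500/0.214 vs
0.267/0.500/0.233).  Exact integer recovery from a family of ~80 plants
is therefore unreliable for $c \ge 2$, and the package's own seeded
recovery experiment in the test suite measures exactly that.  Reports
should quote the profile, not just $\hat{c}$.

## Linkage utilities

Map distances convert through Kosambi
($d = 25\,\ln\frac{1+2r}{1-2r}$), Haldane ($d = -50\,\ln(1-2r)$) or
Morgan ($d = 100r$) functions, with exact inverses (round trips agree
below $10^{-12}$).  Two-point recombination is estimated by maximising
the multinomial likelihood of marker-by-gene counts with expected
frequencies computed by the transmission engine, so segregation
distortion from gametic selection is part of the model rather than a
bias.  The genotype at the gene itself is read from the
pollen-fertility class (`infer_gene_genotype()`), mirroring how
semisterile mapping populations are scored; ambiguous plants are
flagged and should be excluded by the caller.

Numerical choices: the likelihood is evaluated on an $r$-grid of step
$10^{-3}$ only to bracket the optimum, then refined with
`stats::optimize()` (golden-section with parabolic interpolation) to
machine tolerance — the profile in $r$ is smooth and unimodal for these
designs, so a finer grid would add cost without accuracy.  Confidence
intervals are profile-likelihood regions at a log-likelihood drop of
$\tfrac12\chi^2_{1,0.95} = 1.92$, found by root bisection on each side
and clamped to $[0, 0.5]$.  Both marker phase interpretations are
scored and the better one kept, making the estimate invariant to
swapping the marker's allele labels.  Fine-mapping intervals are
delimited by the closest marker on each side of the gene showing at
least one recombinant; all-zero counts return a "cosegregating" status
rather than an error.

## Exact and chi-square tests

The segregation chi-square drops zero-expectation classes and reduces
the degrees of freedom to (retained classes − 1), because
$(O-E)^2/E$ is undefined at $E = 0$; an observation in such a class is
a model violation and errors with the class named.  For the 90-plant
two-locus table this gives $\chi^2 = 2.467$ on 7 df, $P = 0.930$.

Fisher's exact test is assembled from log hypergeometric point masses
(`dhyper(log = TRUE)` + log-sum-exp), with one-sided tails and the
two-sided minimum-likelihood convention; the default is two-sided,
which is what reproduces the published transgene-line p-values, and the
implementation is cross-checked in the tests against both exhaustive
enumeration of the support and `stats::fisher.test()`.

## The synthetic-data generator

`simulate_population()` draws plants by sampling egg and sperm from the
parents' gamete distributions (sterile pollen is rejected according to
the rules, softened by rescue), then scores `grains = 200` pollen
grains per plant — the scoring depth of the motivating experiments —
with beta-binomial noise.  Default overdispersion is `rho = 0.01`: the
within-class spread of published fertility histograms is visibly wider
than binomial, but no estimate is published, so this is a fixed modest
choice rather than a fitted value.  Missing genotype calls are injected
uniformly at random (default rate 0).  One user seed expands into
separate substreams for genotypes, pollen counts and missingness, so
enabling one nuisance never perturbs another stream and simulated
tables are bit-for-bit reproducible.

What the generator emulates: selfed two-locus populations of the size
used for segregation tables (~90 plants), single-locus semisterile
mapping families, high-resolution fine-mapping screens (thousands of
plants, sub-cM marker spacing), and T1 transformant families.  What it
does not emulate: crossover interference beyond the map function's
implicit correction (crossovers are independent Bernoulli events per
interval — adequate for two-point work, wrong for multipoint),
genotyping error (as opposed to missingness), variation in grains
scored per plant, pollen competition, or any female-side viability
dynamics.  Passing tests therefore demonstrate correctness of the
transmission arithmetic and estimator calibration under the stated
model, not robustness to these unmodelled features of field data.

Problem sizes used by the packaged experiments were chosen to mirror
the study designs they emulate: 90-plant populations for model
selection (200 replicates), 80-plant T1 families for copy-number
recovery (200 replicates), 1000-plant backcross populations for
confidence-interval calibration (300 replicates), and 1901- or
3380-plant screens for fine mapping.

## Scope and limitations

* Two alleles per locus, no mutation, no polyploidy; the rule engine
  expresses gametic (not zygotic) selection, though penetrance below 1
  is supported and untested by the motivating data (the observed zero
  count in the doubly-null class is consistent with penetrance 1 but
  does not bound it tightly).
* Population-level propagation (`propagate()`) excludes individuals
  with no viable male gametes from reproduction with a warning and
  renormalises; a population consisting entirely of such plants is an
  error.
* Copy-number estimates above 1 are weakly identified (see above).
* Physical coordinates, marker ordering and multipoint mapping are out
  of scope.
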