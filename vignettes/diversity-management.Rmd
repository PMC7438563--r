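---
title: "Managing genetic diversity under genomic optimal contribution selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing genetic diversity under genomic optimal contribution selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocsim)
```

## The problem

A closed breeding population that is selected on estimated breeding values
loses genetic diversity in two ways: through the deliberate concentration of
parentage in the best families, and through ordinary genetic drift. Optimal
contribution (OC) selection controls this loss by choosing parental
contributions `c` that maximize genetic gain subject to a ceiling on the
*group coancestry* `c'Gc/2`, where `G` is a relationship matrix over the
selection candidates. When `G` is built from genomic marker data rather than
pedigree, the choice of *which* genomic relationship matrix to constrain is
not a technicality: different matrices measure different things, and
constraining them produces populations whose diversity differs in kind, not
just in degree.

gocsim is a closed-loop simulator for studying exactly this question. It
generates whole-genome base populations, runs sib-testing breeding schemes
with SNP-BLUP selection and OC mating under seven alternative relationship
matrices, and tracks two complementary measures of inbreeding on independent
marker panels.

## Two faces of inbreeding

Both measures compare current allele frequencies `p_t,k` at panel loci
against the frozen generation-0 frequencies `p_0,k`:

* **Heterozygosity loss**
  `F_hom = 1 - mean_k[H_t,k / H_0,k]`, with `H = 2p(1-p)`. This is what
  identity-by-state (IBS) similarity measures; it can be negative when
  frequencies move toward 1/2.
* **Drift**
  `F_drift = mean_k[(p_t,k - p_0,k)^2 / (p_0,k(1 - p_0,k))]`. This is the
  standardized squared frequency change; it is nonnegative and measures the
  irreversible random-sampling component of diversity loss.

Per locus, expanding `H_t` around `p_0` gives the exact identity

```
F_hom - F_drift = 2 * mean_k[ (p_t,k - p_0,k)(p_0,k - 1/2) / (p_0,k(1 - p_0,k)) ]
```

so the two measures differ exactly when frequency *changes* are correlated
with the *initial* position of the frequency relative to 1/2. Random drift
produces no such correlation — under pure random mating `F_hom` and
`F_drift` agree in expectation. A management criterion, however, can create
the correlation deliberately: a constraint that rewards heterozygosity
pushes frequencies toward 1/2 (negative deviation, conserved IBS diversity,
*accelerated* drift), while a constraint on standardized frequency change
holds drift at its target but lets heterozygosity erode faster than drift
alone would predict. `hom_drift_decomposition()` returns both sides of the
identity and the test suite verifies it to machine precision.

## The seven relationship matrices

With `m` the 0/1/2 dosage vector of an individual at `N` panel loci and
`p0` the base frequencies:

| label | definition | measures |
|---|---|---|
| `A` | pedigree numerator relationship (tabular recursion) | expected IBD |
| `G_VR2` | `XX'/N`, `X` standardized `(m-2p0)/sqrt(2p0(1-p0))` | drift |
| `G_VR1` | `ZZ'/sum(2p0(1-p0))`, `Z` centred `m-2p0` | drift (heterozygosity-weighted) |
| `G_0.5` | `(1/N) sum_k 2(m_i,k-1)(m_j,k-1)` — dosages centred at 1, i.e. reference frequency 1/2 | homozygosity (IBS) |
| `G_i(p)` | `YY'/N` with the angular coding `y = 2[asin(sqrt(m/2)) - asin(sqrt(p0))]` | variance-stabilized frequency change |
| `G_ROH` | shared-segment fraction, averaged over the four haplotype pairings, segments above a physical length threshold | realized IBD (long segments) |
| `G_LA` | founder-origin identity probabilities on a thinned locus grid (`g_la`), or a marker/pedigree HMM estimate (`g_la_hmm`) | realized IBD |

All builders return a `relationship_matrix` object that records its measure
type and its positive-definiteness repair class. The repair policy
(`make_positive_definite()`) is deliberately per-class: cross-product
matrices get a fixed `0.01` added to the diagonal (they are rank-deficient
whenever candidates outnumber loci), IBD matrices are left untouched (they
are positive definite by construction), and the ROH matrix — which is not an
inner product and can be indefinite — gets an escalating diagonal addition
starting at `0.05` and doubling until the Cholesky factorization succeeds.

The angular-transform matrix deserves a caveat: `g_ip` codes each genotype
by the variance-stabilizing angular transform of its dosage. To first order
in the frequency change this coding is *proportional* to the standardized
coding of `G_VR2`, but its curvature concentrates weight differently; like
`G_0.5`, constraining it turns out to manage IBS similarity rather than
drift. It is implemented as a plain angular coding of dosages, which is the
simplest member of that family; conclusions about its exact magnitudes
should be treated as implementation-specific.

## Optimal contributions

`solve_oc()` maximizes `c'g` subject to `c'Gc/2 = K`, per-sex sums of 1/2,
and `c >= 0`. On a working set of candidates the equality-constrained
stationary point has the closed form `c = c_min + Pg/lambda`, where `c_min`
is the minimum-coancestry solution, `P` the projected inverse of `G`, and
`lambda` is set so the coancestry constraint binds. Nonnegativity is
enforced by an active-set loop: candidates whose stationary contribution is
negative are removed, and — importantly — removed candidates are re-admitted
when their reduced gradient indicates they would carry positive weight at
the optimum. The test suite checks the solver against a brute-force oracle
that enumerates all active sets on small instances; the re-entry step is
what closes the gap between the classical "discard and repeat" heuristic
and the true constrained optimum. If even the minimum achievable coancestry
exceeds `K`, the minimum-coancestry solution is returned and flagged, and
the schedule marches on — infeasibility is logged, never hidden.

The per-generation targets come from `constraint_schedule()`:
`K_t = K_{t-1} + dF(1 - K_{t-1})`, a constant rate of inbreeding `dF`
relative to the remaining diversity, anchored at the observed group
coancestry of the first managed generation.

## The simulated breeding scheme

Each replicate starts from a base population simulated forward in time
under Wright–Fisher reproduction: default effective size 100, run for 400
generations with gamete-level mutation, on 10 chromosomes of 1 Morgan
(physically 140 Mb each, uniform map). Rather than burning in from zero
variation, the simulator initializes the site-frequency spectrum at its
neutral equilibrium (expected count `theta/i` of sites at derived count
`i`) and lets the forward phase converge the linkage structure; the test
suite checks the realized spectrum and segregating-site count against the
neutral expectations. The final generation is expanded to 2000 founders.

From the segregating sites, four disjoint panels of 7000 loci are drawn:
**M** (markers for GEBV and, usually, management), **Q** (QTL), **N**
(neutral, never used by the scheme — the unbiased monitor), and **D** (an
alternative management panel). QTL effects are scaled so founder true
breeding values have variance exactly 1; phenotypes add environmental
variance 1.5 (heritability 0.4).

Each generation, 2000 offspring are produced; within every full-sib family
half become selection candidates (genotyped, unphenotyped) and half test
sibs (phenotyped). SNP-BLUP is fit to the current generation's test-sib
records — solved in the record dimension (`V = XX' + lambda I`), which is
exact and much cheaper than the marker-dimension equations, and verified in
the tests against both the mixed-model equations and the equivalent GBLUP —
and candidates' GEBVs feed `solve_oc()`. Sires and dams are then drawn for
each offspring independently with probabilities `2c_j`. Scheme labels
follow the `Matrix(EBV, management)` convention: `G_VR2(M,M)` selects on
Panel-M GEBVs and manages a Panel-M `G_VR2`; `A(M,~)` manages pedigree
relationships; `G_VR2(~,M)` replaces GEBVs with random noise to isolate
management from selection.

## What the simulator shows

Running the standard schemes (`standard_schemes()`) for 20 generations with
`dF = 0.005` produces a consistent qualitative picture at every population
scale we have tested:

* `G_VR2(M,M)` holds `F_drift` on the managed panel at almost exactly the
  target rate, but `F_hom` grows several times faster there — the deviation
  `F_hom - F_drift` is strongly positive, and remains positive (attenuated)
  on the untouched neutral panel. Managing standardized frequency change
  conserves drift, not IBS heterozygosity.
* `G_0.5(M,M)` is the mirror image: heterozygosity is conserved or even
  increased (deviation strongly negative) while drift runs at several times
  the target. The same reversal, milder, appears under `G_i(p)` and
  `G_ROH`.
* `G_LA(M,M)` — managing realized IBD — is the only genomic option that
  keeps `F_hom` and `F_drift` moving together on the neutral panel, both
  near the target.
* `A(M,~)` under genomic selection lets neutral drift exceed the
  pedigree-expected rate: pedigree expectations miss the within-family
  selection pressure on the markers.
* Raw gain is highest under the pedigree constraint, but at *matched
  overall inbreeding* the IBD-managed scheme converts diversity into gain
  best — it wins the majority of per-replicate paired comparisons
  (`paired_comparison()`) against every alternative.

Absolute magnitudes — gains in genetic-SD units, the exact inflation of the
pedigree-managed drift rate — are sensitive to design details that the
qualitative contrasts are not: family structure, training-set design and
the realized accuracy of the GEBVs, and population scale. The package
pins these choices explicitly (monogamous initial matings, within-
generation sib training, the constants above) and treats the signs,
orderings and binding-constraint behaviour as the reproducible content.

## A worked example

A reduced-scale run (5 chromosomes, 400 base individuals, 1000-locus
panels, 400 offspring over 15 generations) finishes in a few seconds per
scheme-replicate and already shows every effect above:

```{r example, eval = FALSE}
sim <- sim_config(ne = 50, base_generations = 200,
                  map = genome_map(n_chr = 5), n_base = 400,
                  panel_size = 1000, grid_step = 10)
schemes <- list(
  "G_VR2(M,M)" = scheme_config("G_VR2", "M", "M", n_offspring = 400,
                               generations = 15, n_init_per_sex = 40),
  "G_0.5(M,M)" = scheme_config("G_0.5", "M", "M", n_offspring = 400,
                               generations = 15, n_init_per_sex = 40),
  "A(M,~)"     = scheme_config("A", "M", "none", n_offspring = 400,
                               generations = 15, n_init_per_sex = 40))
res <- run_experiment(experiment_plan(schemes, replicates = 3, seed = 41,
                                      sim = sim))
res$rates[res$rates$panel == "M",
           c("scheme", "dF_hom", "dF_drift", "dev_f")]
#>       scheme       dF_hom dF_drift      dev_f
#>   G_VR2(M,M)  0.038248469 0.005096  0.3408039
#>   G_0.5(M,M) -0.002814309 0.088282 -0.7517101
#>       A(M,~)  0.002345565 0.024724 -0.2624155
```

The managed-panel contrast is unmistakable even at three replicates: the
drift-managed scheme holds `dF_drift` at the 0.005 target while losing
heterozygosity seven times faster, and the homozygosity-managed scheme
*gains* heterozygosity while drifting at eighteen times the target.

## Scale presets and reproduction

`experiment_plan()` ships two replication presets (`desk` = 10,
`full` = 100) at identical model constants. The headline reproduction
script, `scripts/acceptance.R`, runs the five contrasting schemes at the
full model constants with 7 replicates — the largest count whose measured
single-CPU wall time (about 100–130 s per replicate for the base
population plus five 20-generation schemes) fits comfortably in a
20-minute budget. Replication count affects only the sampling error of the
reported means, never the model; the per-value replicate count is recorded
in the JSON it writes:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

* The linkage-analysis matrix used for management (`g_la`) reads founder
  origins from the simulator's bookkeeping on a thinned locus grid; the
  marker-based HMM estimator (`g_la_hmm`) is provided and tested against
  it, but is too slow to sit inside the management loop at full scale.
* `g_ip` is one concrete member of the angular-coding family (see above);
  its qualitative sign reversal is robust, its magnitudes are not.
* Discrete generations, equal sex numbers, a single additive trait, no
  dominance or epistasis, no genotyping error.
* Mutation is switched off after the base population: inbreeding metrics
  measure loss of *initial* diversity only.
* The forward-in-time base generator converges linkage disequilibrium over
  a few hundred generations but inherits its site-frequency spectrum
  partly from the analytic initialization; very rare variants are
  correspondingly close to their neutral expectation.
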