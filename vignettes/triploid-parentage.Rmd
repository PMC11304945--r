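---
title: "Assigning triploid offspring to diploid parents: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning triploid offspring to diploid parents: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripar)
```

## The biological setting

Triploidy in farmed finfish is induced by blocking the extrusion of the
second polar body after fertilisation: the egg keeps both products of
meiosis II, so the offspring carries two maternal chromosome sets and one
paternal set. Such fish are sterile and commercially valuable, but their
breeding values must be estimated through sibs, which requires recovering
the pedigree of mixed-family batches from marker genotypes. Diploid
parentage software cannot score a three-allele genotype; this package
builds the triploid transmission model from first principles.

## Transmission model

Consider one co-dominant marker. The sire transmits each of his two alleles
with probability 0.5. The dam's double contribution depends on whether a
crossover occurred between the marker and the centromere during meiosis I:

* homozygous dam `AA`: always an `AA` gamete;
* heterozygous dam `AB`: gametes `AA` and `BB` each with probability
  `0.5 * (1 - r)` (no crossover: sister chromatids are identical), and the
  heterozygous gamete `AB` with probability `r` (crossover: the retained
  polar body complements the egg).

`r` ranges from 0 (marker at the centromere) to 1 (tip of the chromosome
arm under full interference, i.e. exactly one crossover per arm — close to
reality in salmonids). `meiosis_oracle()` enumerates this model exactly and
is the reference implementation against which everything else is tested.

### Genotype classes

A triploid genotype is classified as `AAA` (one distinct allele), `ABB`
(the singleton maps to letter A, the duplicated allele to B) or `ABC`
(three distinct alleles, lexicographic letter order — the order only
affects bookkeeping, since the three-allele class is symmetric). Parent
genotypes are re-expressed through the offspring's letters; any parent
allele the offspring does not carry maps to one extra "other" letter. This
letter algebra is what lets a small, closed table cover multiallelic
markers: two distinct foreign alleles behave identically to a homozygous
foreign genotype because neither can ever match the offspring.

### Likelihood tables

`triploid_likelihood()` returns `P(offspring genotype | sire class, dam
class)` as closed-form cells in the allele frequencies `fA, fB, fC` (taken
from the offspring population being assigned — the population the
frequencies describe by construction; a parent matrix can be passed instead
for sensitivity analyses), the recombination rate `r`, and an error floor
`e`. Three structural facts, each verified against the enumeration oracle
in the test suite:

* every cell is **degree 1 in `r`** (the dam gamete probabilities are);
* cells for missing parents are **Hardy–Weinberg marginals** of the
  non-missing cells (checked to 1e-12 over a 20 × 21 grid of `(fA, r)`);
* an `ABC` offspring requires a recombinant maternal gamete, so every
  compatible cell of that table carries a factor `r` — including the
  sire `AA` × dam `BC` cell, which equals `r` (the dam must transmit both
  of her alleles); this is forced by the model and by the table's own
  Hardy–Weinberg marginal `2 fB fC r`.

Combinations that are impossible under the model are given the constant
`e` (default 0.01) instead of 0, so one genotyping error cannot veto a true
pair; `e` is deliberately crude — any small non-zero value behaves
equivalently, which is why it is a constant and not an estimated rate.

### Exclusion tables

`triploid_mismatches()` counts 0, 1 or 2: whether the offspring genotype is
compatible, incompatible with one parental genotype (or only with their
combination), or incompatible with each parent taken alone. Recombination
is treated as always possible, so exclusion is **independent of `r`** — an
invariant asserted in the tests. The classic single-parent signal is the
opposed homozygote: a `BB` parent cannot have an `AAA` offspring whichever
role it takes.

## Scoring and assignment

`score_all_pairs()` materialises per-marker lookup arrays
(`build_marker_tables()`) and sums log10 likelihoods and mismatch counts
over markers for every offspring × (sire, dam) combination. Markers where
the offspring call is missing are skipped; missing parent calls use the
marginal rows. The *mean* (not the sum) of log10 likelihoods is reported so
offspring with different missingness remain comparable. Internally the sum
is computed as a 16-term dense matrix contraction through BLAS, with a
direct gather kernel kept as an independent cross-check; the two agree to
machine precision in the tests. Transmission probabilities of exactly zero
can only occur at the `r` boundaries 0 and 1; their logs are floored at
-400 per marker so pair scores stay finite and rank correctly.

### Likelihood method

The best pair is accepted when `delta` (best minus runner-up mean log10
likelihood; the runner-up is simply the second-best pair overall) exceeds a
threshold `T`. `T` is the `1 - error_rate` quantile (default tolerated
error rate 5%) of the delta distribution of `max(1000, n_offspring)`
pseudo-offspring gene-dropped from the marker allele frequencies —
unrelated to every candidate, with missingness profiles copied from real
offspring, transmitted through the same meiosis model at the scoring `r`.
This calibration controls the probability of accepting an offspring that is
related to none of the candidates. Exact ties for the best pair are never
assigned. Two consequences observed in the package's own experiments and
worth knowing:

* when negatives share one true parent with the candidates (a masked sire
  but present dam, say), half-sib pairs score close to true pairs and the
  realised FDR can exceed the nominal rate substantially — the same
  qualitative overshoot the method family shows in published validations;
  the test suite therefore asserts the FDR bound on negatives unrelated to
  all candidates, which is what the null models;
* on low-information panels (100 markers with MAF drawn from
  U(0.05, 0.5)), one or two true pairs per 500 offspring can fall just
  under `T` and stay unassigned, so plateau sensitivities of 0.99–1.0
  rather than exactly 1.0 are expected; the misses are unassignments, not
  errors.

### Exclusion method

The pair with the fewest mismatches is accepted when unique and when its
count does not exceed an allowance. The automated allowance
(`auto_mismatch_threshold()`) exploits the bimodality of per-offspring
minimum mismatch counts: true pairs accumulate only error-induced
mismatches (about `2 e` per marker at most), unrelated pairs an order of
magnitude more, so the allowance is the largest count before the first
empty histogram bin after the low cluster. If the histogram has no such
valley the allowance falls back to the 99.9% quantile of
`Binomial(n_markers, 2e)` — an upper bound on a true pair's error-induced
count. The valley rule is a reconstruction of behaviour the original
software documents only in outline; the fallback makes it safe on
degenerate histograms (all zeros: allowance 0; a low cluster not anchored
at zero is still found; a single continuous mode triggers the binomial
rule).

### Single-parent comparator

`grashei_assign()` implements the sex-blind, parent-wise exclusion strategy
(after Grashei et al. 2018) used as a baseline: a parent is excluded at a
marker only when it is impossible in *both* roles with the other parent
unknown (opposed homozygotes); parents are ranked per offspring by
exclusion proportion; the acceptance threshold is the **lowest third-ranked
proportion observed across the whole offspring set**, and the two top
parents strictly below it are retained. The dataset-wide reading of the
threshold is deliberate: it is the only reading that produces the
documented failure mode — with ~200 candidates and 100 biallelic markers,
some offspring somewhere almost surely has an unrelated parent with zero
opposed homozygotes, the threshold collapses to zero, and *nothing* is
assigned, while a per-offspring threshold would assign most offspring. At
200 markers the threshold becomes positive but remains the minimum of a
very large number of binomial draws, so replicate-to-replicate sensitivity
is volatile (roughly 0.83–1.0 per replicate in the package's experiments) —
exactly why pair-wise scoring with parent-sex information is preferable on
small panels. Dam/sire roles of a retained pair are oriented by dam-specific
exclusions (e.g. an `ABB` offspring cannot have an `AA` dam, but can have an
`AA` sire); since the comparator uses no sex information, its pairs are
evaluated without parent order.

## Simulator

`simulate_dataset()` draws per-marker MAFs (fixed, or uniform over a
range), Hardy–Weinberg diploid parents, matings (full factorial with
uniformly sampled pairs, random pairs, or an explicit cross list for
partial factorials), offspring through the meiosis model at a chosen true
`r`, genotyping errors, and per-sex parent masking
(`floor(fraction * n)` kept). Genotyping error replaces each allele copy,
with the stated probability, by a uniform draw from the marker's two
alleles — so half the events are silent and the effective corruption rate
is half the nominal one; this mirrors the stated error model of the
validation experiments and is worth remembering when comparing error
rates. Errors are injected in offspring only; parent genotypes are taken
as delivered (in real datasets they carry their own errors upstream of this
package). Every piece accepts explicit seeds; replicate `k` of an
experiment uses `seed + k`.

What the simulator does *not* emulate: linkage between markers (markers
are independent), per-marker heterogeneity in `r`, array-specific artefact
structure, and parent-genotype errors. Passing simulations therefore
demonstrate correctness of the transmission model and the decision rules,
not robustness to every failure mode of a real genotyping pipeline — the
marker-quality ranking (`rank_markers()`: call rate, then MAF, then name)
is provided precisely because real panels are not exchangeable.

## Experiment grids and default problem sizes

`run_experiment()` crosses methods × marker counts × masking fractions ×
recombination parameters × replicates and emits one tidy row of metrics
(sensitivity = TP/positives, FDR = FP/(TP+FP), specificity = TN/negatives;
a pair containing exactly one true parent counts as a false positive) per
combination. The package's acceptance experiments use: a 100 × 100 full
factorial with 1,000 offspring and 100 or 200 SNPs at MAF 0.5 (five
replicates, pooled) for the method comparison; a 98-sire × 190-dam
population with 500 offspring for the marker-count curve (192 and 384
markers, three replicates) and for the recombination sweep (100 markers,
MAF ~ U(0.05, 0.5), true r of 0.25/0.50/0.75, parameter window 0.40–0.70).
These sizes keep a full run in minutes on one CPU while leaving the
binomial noise on each pooled estimate well below the effect sizes being
checked.

## Numerical choices and edge cases

* log10 is the score scale; thresholds are scale-consistent.
* Partially missing calls (e.g. `A/NA/B`) are treated as fully missing —
  a placement in the tables would require knowing which copy is absent.
* A marker with every call missing is dropped from scoring with a warning;
  an offspring with no usable marker is flagged unassignable.
* Frequencies of alleles seen in parents but absent from the offspring
  population are 0; the corresponding classes exist in the tables and
  simply never gain likelihood from missing-parent marginals.
* Exact score ties (possible with duplicated parent genotypes) always
  yield "unassigned" rather than an arbitrary pick.
* `stats::quantile` type 7 (the default) defines the null quantile.

## Known limitations

Diploid offspring, tetraploid parents and higher-ploidy systems are out of
scope. The likelihood threshold and the automated mismatch allowance are
reconstructions of procedures whose originals are documented only in
outline; both are specified precisely here and covered by tests, but they
are not guaranteed to match the original software decision-for-decision.
Real-array genotype data (with linked markers, heterogeneous `r` along
chromosome arms and correlated call-rate structure) will behave somewhat
differently from the simulator; the marker-count safety margins reported by
the experiments should be read with that in mind.
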