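---
title: "Methods and design of msatpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of msatpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpop)
```

## Scope

msatpop implements the population-monitoring analysis used with large
livestock parentage panels — concretely, the 11-locus microsatellite (STR)
panel used for parentage verification in Korean native cattle (Hanwoo):
quality control of raw genotype records, per-locus diversity statistics,
pairwise differentiation between birth-year cohorts, and the non-exclusion
probabilities that quantify the panel's identification power. Because
individual-level genotypes of that population are not public, the package
also contains a first-class synthetic-cohort generator whose parameters are
the quantities the estimators target, so the whole pipeline is testable by
parameter recovery at desk scale.

## Data model

A `GenotypeTable` stores one record per animal: a barcode ID, birth year,
registered sex, two sex-determination marker calls, and two integer
allele-size calls (base pairs) per autosomal locus. Genotypes are unordered:
pairs are stored sorted ascending, and heterozygosity only ever compares the
two values. Sex markers live outside the autosomal panel and never enter any
statistic — they exist solely for the QC screen. Two file dialects are
supported: a simple CSV (one `<locus>_1`/`<locus>_2` column pair per locus)
and Genepop 4.x with 3-digit allele coding (`000` = missing). Reading never
drops a record; every removal happens in the QC cascade with a counted
reason.

## The QC cascade

Stages run in a fixed order: (ii) remove records with any missing autosomal
call; (iii) remove records with an allele outside its locus's inclusive
size window; (iv) remove records whose sex-marker pair contains a value
other than X/Y, contains a missing call, or mismatches the registered sex
(three disjoint reasons, in that priority order); (v) collapse duplicate
barcodes — concordant groups merge into one record (missing calls filled
from any member), discordant groups are dropped entirely; (vi) drop birth
year cohorts with fewer than `minCohortSize` (default 100) survivors. The
order matters (permuting stages changes counts), which is why it is part of
the contract. The `QcReport` satisfies, exactly:

```
final = raw - missing - range - sex - duplicateRecords
        + duplicatesRecovered - smallCohort
```

where `duplicateRecords` counts every member of a multi-record barcode group
and `duplicatesRecovered` the merged representatives added back. Running QC
twice is the identity. Duplicate concordance requires exact equality of all
non-missing genotype calls plus birth year and registered sex; sex-marker
calls are held to the same standard and merged the same way. No mismatch
tolerance is applied because none is defensible without an error model.
The sex rule defaults to the amelogenin-type reading F = {X,X}, M = {X,Y}
but is configurable; allele windows are configuration rather than constants
because fragment-size ranges are chemistry-specific.

## Diversity statistics

For allele frequencies `p_i` estimated by plain call counting (missing calls
excluded from numerator and denominator):

* observed heterozygosity `HObs` — fraction of typed individuals with two
  different calls;
* gene diversity `HExp = 1 - sum(p_i^2)`, with an optional unbiased
  variant `2N/(2N-1) * HExp`. The exact form is the default: at the cohort
  sizes this package targets the difference is below 1e-5, and the exact
  form reproduces published mean lines from printed per-locus values;
* Botstein's polymorphic information content
  `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, computed through power
  sums; `PIC <= HExp` always, with equality only at a monomorphic locus;
* the simple inbreeding coefficient `FIS = (HExp - HObs)/HExp`, undefined
  (NA) at monomorphic loci; and the unbiased within-cohort estimator
  `f = 1 - HObs/Hs` with `Hs = n/(n-1) (1 - sum(p^2) - HObs/(2n))`, the
  form basic-statistics routines in popgen packages report per population.

Panel mean rows are unweighted means over loci — the convention that
reproduces published mean lines exactly from the printed per-locus entries.
Both F_IS estimators are carried side by side: applying the simple formula
to printed H columns does not reproduce typical published per-locus F_IS
values (those generally come from variance-component estimators), so the
package exposes both and forces neither.

## Weir–Cockerham F-statistics

Differentiation uses the Weir–Cockerham (1984) variance components: per
allele, `a` (between populations), `b` (among individuals within
populations) and `c` (within individuals), from observed heterozygote
frequencies with the `nbar`/`n_c` sample-size weights, summed over alleles
and loci. `theta = a/(a+b+c)` estimates F_ST; `f = 1 - c/(b+c)` is the
within-population inbreeding analogue. Multilocus combination is the ratio
of sums, never the mean of per-locus ratios. The simple `(H_T - H_S)/H_T`
statistic is also provided (`htHsFst`); on large balanced samples it tracks
theta closely (correlation above 0.99 in the shipped drift-grid test) but
it is a different estimator, so equality is never asserted. The
variance-component theta is normative because it is the estimator the
field's tooling (hierfstat, and the original derivation it cites) actually
computes.

Pairwise cohort matrices keep raw estimates, which are legitimately
slightly negative near zero differentiation; flooring at zero is purely a
display option (`thetaMatrix(x, floorNegative = TRUE)`, and the CSV writer's
default), matching the convention of reporting `0.0000` in published
matrices. Reports round to 4 decimals. Unequal cohort sizes are handled by
the built-in `n_c` weighting; there is no subsampling.

## Non-exclusion probabilities

All five indices share one probability model: HWE genotypes from the locus
frequencies, unrelated candidates, zero genotyping error, exclusion by
genotype incompatibility only. The normative computation is exact
enumeration over genotype configurations (k alleles give k(k+1)/2
genotypes; candidate sums inside the enumeration are collapsed with exact
inclusion–exclusion identities, not approximations):

* NE-I — probability two unrelated individuals share a genotype;
* NE-SI — probability two full sibs share a genotype (enumeration over
  parent pairs and two Mendelian offspring);
* NE-1P — candidate parent not excluded given only the offspring
  (exclusion iff they share no allele);
* NE-2P — candidate second parent not excluded given offspring and one
  true parent; the admissible-allele set is the offspring alleles the known
  parent cannot explain (both admissible when the known parent could have
  contributed either);
* NE-PP — candidate pair not excluded (excluded iff no choice of one
  allele from each reproduces the offspring genotype).

For NE-I and NE-SI, independent closed forms (`2 S2^2 - S4` and
`1/4 + S2/2 + S2^2/2 - S4/4`) are computed alongside and must agree to
numerical precision inside the functions themselves — that guards against
formula-transcription mistakes in either route. The test suite additionally
checks every index against naive nested-loop enumerations at small k, and
against Monte-Carlo draws. The orderings `NE-PP <= NE-2P <= NE-1P` and
`NE-I <= NE-SI` hold for every frequency vector. The zero-error model is
the simplest defensible default (no published error rate exists for the
reference panel, and the combined products reconcile under it). Combined
panel values are per-column products — the loci sit on different
chromosomes by panel design — and identification accuracy is `1 - NE`.

## Cohort trends

`trendStatistics` computes the diversity block per birth-year cohort
independently (years whose cohort was removed by QC are simply absent) with
both F_IS estimators as columns, and `cohortCensus` tabulates cohort sizes
by registered sex with percentages. Marker-set descriptions sometimes count
13 markers for this panel (11 autosomal plus 2 sex markers); every trend and
statistic here uses the 11 autosomal loci only, since sex markers carry no
diversity information. Concatenating the cohorts and
recomputing reproduces the pooled summary exactly; this consistency is a
shipped test. Plotting is deliberately out of the contract: the long-format
CSV is the interface.

## The synthetic generator

`simulateGenotypes` draws, in a fixed order from one seeded RNG stream:
ancestral frequencies (symmetric Dirichlet, default concentration 0.5 —
chosen once as giving realistically uneven STR spectra with gene diversity
near 0.75–0.85 at the panel's allele counts); per-cohort frequencies under
the Balding–Nichols model (Dirichlet around the base vector with
concentration `(1-F)/F`, so the parameter is the expected F_ST); genotypes
with `P(ii) = p_i^2 + f p_i (1-p_i)`, `P(ij) = 2 p_i p_j (1-f)`; sexes and
concordant sex markers; then QC defects on disjoint record sets with an
exact ledger.

Two drift topologies are provided because they answer different questions.
In `"star"` mode (default) every cohort is an independent draw from the
ancestral pool at `fDrift`, which makes the parameter the direct target of
the pairwise estimator — that is what makes the F-statistics module
testable by recovery, and it is why star is the default. In `"serial"` mode
cohorts drift year on year, so differentiation accumulates with the
birth-year gap; that is the topology behind the demonstration that pairwise
theta grows with the gap, as monitoring data show. Real populations sit
between the two; neither models selection or migration.

Negative `f` (heterozygote excess, as planned-mating populations show) is
supported down to the feasibility bound `-p_min/(1-p_min)` per locus, with
a hard error naming the offending locus. Because pure Dirichlet draws at
realistic allele counts routinely contain frequencies below 5%, strongly
negative `f` requires the optional `minFreq` floor, implemented as a tail
truncation (rare alleles lifted to the floor, the rest renormalised) so the
floor holds exactly while the spectrum keeps its shape. Any floor perturbs
the drawn distribution slightly, so it defaults to off and the
drift-recovery checks run without it.

`hanwooLikeConfig` is the preset that mimics the national dataset's
shape: the real panel with its published allele counts, 23
birth-year cohorts (2001–2023) at the published sizes divided by 100 with a
floor of 50, a cow-biased sex ratio (0.68), defect rates in the published
preprocessing proportions, weak serial drift (0.0007 per year, which puts
pairwise theta in the published 0.0003–0.0081 range across a 22-year span)
and `f = -0.003`. It mimics shape only (the real population's allele
frequencies are not public), and its
scaled cohorts are analysed with `minCohortSize = 50`.

The generator does not simulate pedigrees, linkage or mutation — the
analysis uses none of them. Consequently, passing recovery tests show the
estimators are correct under the stated model; they cannot show robustness
to misspecification (null alleles, scoring drift between chemistry
batches, family structure within cohorts).

## Numerical and testing choices

* Frequencies must sum to 1 within 1e-9 (class validity); enumeration and
  closed forms must agree within 1e-9 inside the NE functions and are
  tested to 1e-12 against independent loop oracles.
* Degenerate inputs: monomorphic loci give `HExp = PIC = 0`, `FIS = NA`,
  and every NE equal to 1; populations with fewer than two typed
  individuals are excluded from variance components with a warning, and
  fewer than two usable populations is an error.
* Recovery tests use 3 Monte-Carlo standard errors from the replicate
  spread. Problem sizes were fixed once as the smallest that make those
  intervals informative: 10,000 individuals per cohort and 20 replicates
  for parameter recovery; 100 random defect designs for ledger equality;
  cohort sizes 100–10,000 (20 stationary cohorts per size) for the
  1/N variance-scaling check, whose log–log slope must be -1 within 0.2.
* The variance-scaling design holds the frequency draw fixed across sizes
  (same seed, identical pre-genotype RNG stream) so the measured spread is
  sampling noise only, which is the claim under test.

## Known limitations

* The QC stage order is the published preprocessing order; other orders
  are deliberately unsupported rather than configurable.
* Published per-locus F_IS values cannot be reproduced from printed H
  columns by the simple estimator, and per-locus NE values cannot be
  re-derived at all without the underlying allele frequencies; the package
  therefore validates combined/mean reconstructions and its own estimators,
  not per-locus published rows.
* Genepop files carry no sex information, so they are an analysis-stage
  format (the export consumed by F-statistics tooling), not a QC input:
  running the sex screen on a Genepop-read table removes every record,
  by design of the screen. CSV is the dialect for full-pipeline runs.
* Enumeration scales as the square of the genotype count; it is exact and
  fast to k = 30 alleles, far above real STR panels, but is not intended
  for sequence-derived hypervariable loci beyond that.
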