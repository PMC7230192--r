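---
title: "Transmission genetics of the mandarin vole neo-XY system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission genetics of the mandarin vole neo-XY system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoxy)
```

## The system being modelled

The mandarin vole *Lasiopodomys mandarinus vinogradovi* carries one of the
strangest sex-chromosome systems known in mammals.  Its sex complex is built
from four chromosome elements, created by at least two recent
autosome-to-sex-chromosome translocations:

* **neo-X1** — X euchromatin fused to autosomal block A1 (the homolog of
  field-vole chromosome MAG13 / mouse MMU18);
* **neo-X2** — X euchromatin fused to autosomal block A2 (MAG17/19 homolog);
* **neo-X3** — a small acrocentric consisting of block A2 only;
* **neo-Y** — a small acrocentric consisting of block A1 plus X-homologous
  *repeats* only: sequencing shows no X synteny, so the package counts its X
  dosage as zero.

All males share one karyomorph, **KI** (neo-X1/neo-X3/neo-X3/neo-Y,
2n = 48).  Females come in three: **KII** (neo-X1/neo-X2/neo-X3, 2n = 47),
**KIII** (neo-X2/neo-X3/neo-Y, 2n = 47) and the rare **KIV**
(neo-X1/neo-X1/neo-X3/neo-X3, 2n = 48), observed at roughly 47%, 47% and 6%
of females.  KIII females *carry a Y* yet are fertile females — the
signature of an XY-female system as in wood and collared lemmings.

`neoxy` asks the quantitative question behind that claim: which
genotype-to-sex rule, combined with plain meiotic segregation, predicts the
progeny actually produced in the breeding colony?

## Genotype-to-sex hypotheses

Four total maps from sex complement to phenotypic sex are implemented
(`phenotype()`):

* `standard` — male iff a neo-Y is present (conventional Y dominance);
* `mech_a` — neo-X2 carries an epistatic suppressor (locus B) of the
  dominant male trigger (locus A) on the neo-Y: male iff Y present and
  neo-X2 absent;
* `mech_b` — neo-X1 carries a locus (D) complementing the male trigger (C)
  on the neo-Y, absent/inactive on neo-X2: male iff Y and neo-X1 both
  present;
* `mech_c` — the trigger sits on neo-X1 itself, inactive in double dose and
  suppressed by neo-X2: male iff exactly one neo-X1 and no neo-X2.

The three XY-female mechanisms agree on every *viable* genotype reachable
from the observed crosses (the package proves this by enumeration in its
test suite), so breeding data cannot distinguish them — but all three
disagree with `standard` on KIII, which is precisely the discriminating
observation.

## Segregation model

Dams whose three sex elements pair as a trivalent are assumed to resolve it
by **alternate (balanced) segregation** into exactly two gamete classes:

* KII (trivalent neo-X1 – neo-X2 – neo-X3): gametes {neo-X1, neo-X3}
  (probability `s_KII`, default 0.5) or {neo-X2};
* KIII (trivalent neo-Y – neo-X2 – neo-X3): gametes {neo-X2}
  (probability `s_KIII`) or {neo-X3, neo-Y};
* KIV and KI form bivalents: KIV dams give only {neo-X1, neo-X3}; KI sires
  give {neo-X1, neo-X3} or {neo-Y, neo-X3} sperm.

This is a design choice, but not an arbitrary one: it is the *unique*
two-class rule that generates all the offspring classes actually observed
(KIV, KI, KII, KIII from KII dams; KII, KIII, KI from KIII dams) without
invoking nondisjunction — which the XY-female reading explicitly avoids.
Under the `standard` hypothesis the engine instead mirrors the bookkeeping
that hypothesis historically used: the small acrocentrics are unidentifiable
and dropped, KIII dams are treated as a lone neo-X2 producing a nullosomic
gamete class, and zygotes are written neo-X1/0-style.

Two selection knobs complete the model:

* `w_Y` — relative fertilization success of neo-Y-bearing over
  neo-X1-bearing sperm, *conditioned on the dam's karyomorph* (default 1).
  It acts at fertilization because the reported distortion depends on which
  female is fertilized, which a sire-side meiotic drive could not produce.
* `v_X1X1` — relative viability in [0, 1] of double-neo-X1 zygotes
  (default 1), encoding the proposed lower viability of KIV females.

Viability rules: under any XY-female mechanism the only strictly lethal
class is the zygote with no X euchromatin (neo-Y/neo-Y).  Under `standard`,
rescuing the observations forces three lethal classes: zygotes with no
X-bearing element, neo-X2/neo-Y males, and the monosomic products of a
nullosomic gamete (neo-X1/0, neo-Y/0).  That load — 75% of KIII-dam zygotes
and 25% of KII-dam zygotes — is itself one of the arguments against the
standard reading, and `nonviable_fraction()` computes it.

```{r}
cross("KII", "KI", hypothesis = "mech_a")
expected_sex_ratio("KIII", "KI", "mech_a")
nonviable_fraction("KIII", "KI", "standard")
```

## Likelihood, fitting, and hypothesis comparison

`cross_log_likelihood()` factorizes each dam-karyomorph row of a progeny
table into a binomial term for the sexed offspring (success probability =
expected male share among viable offspring) and a conditional multinomial
term for the karyotyped daughters.  The factorization treats karyotyping as
a simple random subsample of daughters — the colony karyotyped 64 of 196 —
which leaves the class distribution unchanged, so no extra parameters are
needed.  An observed class with model probability zero gives `-Inf`: the
hypothesis is *rejected by an impossible observation*.  This is exactly what
happens to `standard`, which predicts only-KII daughters from KIII dams
while 6 KIII daughters were observed.

```{r}
compare_hypotheses(load_fixture("progeny"))
```

`fit_parameters()` maximizes the likelihood by deterministic bounded grid
refinement — log-spaced over [1e-3, 1e3] for sperm weights, linear over
[0, 1] for segregation and viability parameters — chosen over a
quasi-Newton optimizer for exact reproducibility at this tiny problem size.
Profile-likelihood 95% intervals use the chi-square(1) cutoff (a drop of
1.92 log-units); a parameter whose profile is flat over its whole range is
flagged non-identifiable in the metadata rather than raising an error.
AIC (2k − 2 logL) ranks hypotheses because the mechanisms are not nested in
`standard`; with no free parameters the comparison reduces to a pure
likelihood ranking.

Fitting the colony data with a free `wY_KII` lands above 1 — the direction
of the reported excess of Y-fertilized classes (sons and KIII daughters) in
KII dams.  No published estimate of this weight exists, so the package's
tests check only sign and synthetic-data recovery (±20% at ~2000
offspring), not a target value.

## Exact statistics

The tests applied to the colony counts are implemented from first
principles in `chi2_gof()`, `fisher_exact_2x2()`, `fisher_exact_rxc()`,
`binomial_two_sided()` and `two_sample_t()`; the standard R implementations
serve as independent cross-checks in the test suite, never as the
implementation.  Numerical choices worth stating:

* **No continuity correction** anywhere: recomputing the published
  sex-ratio statistics gives 11.28 and 5.62 against printed 11.2 and 5.66 —
  the uncorrected statistic matches far better than the corrected one, and
  is treated as authoritative (the <1% differences are rounding).
* **Two-sidedness by probability ordering** for every exact test (sum of
  outcome probabilities not exceeding the observed one), stated explicitly
  because definitions differ across software; ties use a 1e-7 relative
  tolerance.
* **Log-space probabilities** in all enumerations, so tables with n ≈ 300
  do not overflow factorials.
* The r×c Fisher test enumerates *all* tables with the observed margins
  (recursively, last row and column forced) behind a 10^7-table guard that
  aborts with advice rather than running unbounded.
* The exact binomial for 7 sons in 7 offspring gives p = 0.015625; the
  published table prints p = 0.070 for that row by an unstated construction
  that an exact binomial cannot reproduce.  The package reports its own
  exact value and documents the discrepancy rather than matching it.

## Population simulation

`step_generation()` / `run_trajectory()` / `deterministic_equilibrium()`
iterate the karyomorph composition of a closed population:
non-overlapping generations, every dam mated to a KI male (the only viable
male genotype under XY-female rules — asserted, not assumed, each
generation), per-dam offspring output proportional to a per-karyomorph
fecundity multiplier times the viable-zygote fraction of her cross.
Deterministic mode iterates the expectation map on female karyomorph
frequencies; stochastic mode draws Poisson offspring numbers and
multinomial classes, fully determined by one integer seed, with random
thinning above a carrying capacity.

The simulator quantifies the polymorphism-maintenance question.  Under
fully Mendelian defaults the KIV frequency can only rise (it breeds true
and is over-produced), so the observed 6% rarity *requires* selection —
reduced `v_X1X1` and/or reduced KIV fecundity (none of the four KIV dams in
the reproductive-success cohort bred).  Iterating to equilibrium:

```{r}
deterministic_equilibrium("mech_a", cross_params(v_X1X1 = 0.2))$frequencies
```

A double-neo-X1 viability around 0.2 reproduces the observed 47/47/6%
female composition almost exactly — a result the package computes, not a
calibration target; no parameter was tuned to it.

## Synthetic breeding colonies

`simulate_breeding_experiment()` replaces the live colony: dams of chosen
karyomorphs, litter totals from a negative binomial (mean 8.6 = 327
offspring / 38 dams; dispersion size 10, a moderate overdispersion chosen
once as realistic for cumulative vole litters, since no per-litter table is
published), offspring classes i.i.d. from the viable cross distribution,
and a seeded simple random subsample of daughters karyotyped (default
fraction 0.33 ≈ 64/196).  What it deliberately does *not* emulate: litter
random effects (a toggleable future extension; offspring are independent
within dams), maternal age or parity structure, and survival to weaning as
a separate process — the model draws surviving offspring directly.  Tests
passing on synthetic data therefore demonstrate correctness of the
machinery and parameter recovery under the stated sampling model, not
robustness to family-level overdispersion in real colonies.

## Problem sizes and determinism

Everything is desk-scale: cross tables have at most 4–6 zygote classes, the
full r×c enumeration for the published 2×3 daughter table visits a few
hundred tables in well under a second, grid-refinement fits evaluate a few
thousand likelihoods, and the simulation studies in the test suite use
populations of tens to hundreds and 200–1000 replicates.  All stochastic
paths flow through explicit integer seeds; deterministic mode contains no
randomness at all.

## Known limitations

* Recombination within the neo-sex chromosomes and multivalent geometries
  beyond the two-class alternate rule are out of scope.
* The molecular identity of the trigger/suppressor loci, and dosage
  compensation, are not modelled; the mechanisms are alternatives, not a
  resolved answer, and the data cannot separate `mech_a`/`mech_b`/`mech_c`.
* The evolutionary dynamics of the distortion weight `w_Y` itself (why
  selection might favor son-biased fertilization in a female-biased
  population) are discussed in the literature but not simulated here.
* One reading ambiguity is left to the user: the all-son progeny of KIV
  dams can be produced either by Y-sperm advantage (`w_Y[KIV]` > 1) or by
  reduced double-neo-X1 zygote viability (`v_X1X1` < 1); both knobs exist
  and the data at n = 7 cannot separate them.
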