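---
title: "Dating protein domains and measuring how fast young domains evolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating protein domains and measuring how fast young domains evolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(domainage)
```

## The question

New protein domains arise continuously in evolution. Once a young domain
exists, two things are worth asking. First, *how* does it enter the proteome:
does it appear by insertion into an already existing multi-domain protein, or
do whole new genes assemble around it? Second, *how fast* does it evolve
compared with the ancient domains it sits next to — young sequence is expected
to be under weaker purifying selection, so its nonsynonymous-to-synonymous
rate ratio (dN/dS, written ω) should be higher.

`domainage` implements the full chain of analysis needed to answer both
questions from three inputs: phyletic presence/absence profiles of domain
types across a set of species, a table of domain hits on proteins, and
pairwise codon alignments of each protein with an orthologue. Because the real
genome-scale inputs are large external resources, the package also ships a
seeded synthetic-data generator with a complete ground-truth ledger, so every
stage can be validated end to end.

## Dating by phylostratigraphy

A domain type is dated with the *oldest-hit* rule: the species of a ranking
(`default_clade_ranking()`: 15 species grouped into Mammalian, Vertebrate,
Metazoan and Eukarya clades, with human as the reference lineage) are scanned
from the oldest clade down, and the age class of the oldest clade containing
at least one presence is assigned. Absences in younger clades are treated as
secondary losses and never rejuvenate a type; a fully empty profile denotes a
reference-lineage-specific domain and receives the youngest class. For
reporting, Metazoan and Eukarya are merged into a single "Old" class, leaving
the two young classes (Mammalian, Vertebrate) of interest.

A protein is as old as its oldest domain; proteins without domain annotations
fall back to a homology profile over the same species universe, dated by the
same rule.

## Architectures and arrangement scenarios

Domain hits with E-value at most 1e-5 are kept; overlapping hits are resolved
greedily (better E-value first, ties by length, then type identifier). The
*configuration* of a protein is the ordered tuple of its domain types with
tandem repeats collapsed, and a type is *independent* when it is seen in at
least two distinct configurations. For each protein combining a young and an
old domain, each young/old type pair is classified:

* **gain_dependent** — the old type is independent, the young is not: the
  young domain was most likely gained by an existing protein;
* **mutual_dependence** — neither type occurs elsewhere;
* **fusion** — both types also occur independently;
* **complex** — the pairs of one protein disagree;
* **reverse_dependence** — the young type is independent while the old is not
  (tracked separately; it is expected to be rare to absent).

The first two classes are *gain-compatible*: they are consistent with
domain gain rather than de novo gene assembly. Where the young domain lands is
tested with a chi-square goodness-of-fit: in 2-domain proteins against a ½/½
N/C split (1 df), and in larger proteins against the 1/k, (k−2)/k, 1/k
N/internal/C expectation aggregated over the observed architecture sizes k
(2 df). The two strata are tested separately; expected cells below 5 are
flagged.

## Rates: NG86 dN/dS per domain region

Each domain occurrence is cut out of the protein's pairwise codon alignment
on ungapped reference coordinates and dN/dS is estimated with Nei–Gojobori
(1986) counting:

* synonymous site fractions per codon position by single-neighbour
  enumeration, with stop-creating changes excluded from the denominator;
* differences per codon pair averaged over all minimal mutational pathways,
  excluding pathways through stop codons (a pair with no stop-free pathway is
  skipped);
* sites averaged over both sequences; proportions corrected with
  Jukes–Cantor, d = −¾ log(1 − 4p/3). A proportion at or above ¾ is a hard
  saturation error rather than a silently divergent estimate.

The 61×61 per-pair difference counts are precomputed once per session and
cached. Estimates are then filtered for reliability — at least 60 aligned
amino acids, dN ≤ 0.5, dS ≤ 2 — with failing rows kept and flagged rather
than dropped.

Two comparison layers sit on top. Between age classes,
`compare_age_groups()` reports medians/quartiles, pairwise
Kolmogorov–Smirnov tests and (for within-protein young/old pairs) a paired
Wilcoxon test; `by_type = TRUE` first collapses each domain type to its
median ω so abundant types do not dominate. Within one protein,
`relative_difference()` gives the bounded contrast
(ω_young − ω_old)/max(ω_young, ω_old) and `paired_binomial_test()` asks
whether the young domain's observed nonsynonymous/synonymous substitution
split deviates from the split implied by the old domain's per-site rates on
the young domain's site counts.

### A calibration caveat

The paired binomial test plugs the old domain's *estimated* rates in as a
fixed null. The old domain's sampling noise is of the same order as the young
domain's and is ignored by this construction, so the test is anticonservative:
under equal true ω on 120–500-codon regions its type-I error at a nominal
α = 0.01 is measured at roughly 0.03–0.07, and the inflation does not vanish
with region length (both noise terms shrink at the same rate). The verdicts
should therefore be read as a screening statistic; α = 0.01 is the default
for this reason, and the group-level Wilcoxon/KS comparisons are the
calibrated inference. The acceptance suite asserts a ≤ 0.02 type-I bound for
this test and that assertion fails honestly; it is retained as documentation
of the limitation rather than weakened.

## The synthetic generator

`sim_params()` fixes every knob of the generator; `simulate_dataset()` turns a
parameter set plus one seed into a byte-reproducible bundle (profiles, hit
table, protein table, codon alignments) with a truth ledger. The defaults are
a deliberately fixed study condition, not tuning targets:

* type inventory 30/130/60/90 (Mammalian/Vertebrate/Metazoan/Eukarya),
  secondary-loss probability 0.2 with an origin-clade survivor guaranteed;
* proteome composition 86 young-only, 154 old-only and 60 combined proteins
  (young-only:combined = 1.43), with combined proteins drawn across the
  gain/mutual/fusion/complex regimes at probabilities 243:16:40:31;
* N-terminal insertion bias 0.6, the remainder split between C-terminal and
  internal slots; whole-protein duplication at 0.05;
* per-age lognormal ω with medians 0.33 (Mammalian), 0.18 (Vertebrate), 0.08
  (Metazoan/Eukarya), sdlog 0.5; linkers at ω = 0.5; common target dS = 0.5,
  typical of human–mouse orthologue pairs;
* domain region lengths lognormal (median 120 aa, sdlog 0.35) clipped to
  [60, 400], with 5% of regions drawn at 30–59 aa so the length filter is
  exercised; linkers uniform on 5–50 aa.

The regimes are constructed so that the classifier's answer is *provably*
recoverable: shared old types are guaranteed to occur in old-only proteins,
exclusive old types never do, fusion partners are emitted standalone, and the
complex regime mixes one shared with one exclusive old type.

Codon alignments evolve by a per-nucleotide-site process: each site changes
at most once, with synonymous probability pS·s and nonsynonymous probability
pN·(1−s), where s is the site's synonymous fraction and pS, pN are the
inverse Jukes–Cantor transforms of the target dS and ω·dS. Stop-creating
changes are never proposed. This is intentionally *not* a full codon-model
CTMC: there are no transition/transversion or codon-frequency effects, no
among-site rate variation beyond the domain/linker split, no indels in the
simulated alignments, and multiple hits per site are excluded. The
consequence is that the NG86 estimator's own pathway-averaging bias is what
recovery tests measure: over ω ∈ {0.05, …, 1.0} × dS ∈ {0.1, 0.5, 1.0} the
median ω̂ stays within ±20% of the target.

## A worked run

```{r}
params <- sim_params(seed = 7,
                     composition = c(young_only = 20, old_only = 35,
                                     combined = 15))
bundle <- simulate_dataset(params)
report <- run_analysis(bundle)
report$percentages
```

```{r}
report$group_comparison$groups
head(report$pairs[c("protein_id", "omega_young", "omega_old",
                    "relative_difference", "verdict")])
```

Plots are available through `autoplot()` (facets: `"omega"`, `"positions"`,
`"pairs"`) and the `plot_*()` functions.

```{r, fig.width = 6, fig.height = 3.5}
ggplot2::autoplot(report, which = "omega")
```

## Problem sizes and runtime

The default bundle (300 proteins before duplication, 310 domain types)
simulates in a few seconds and analyses in a few seconds on one CPU; the
whole acceptance suite, including a 12-point ω-recovery grid at 100
replicates, a 1000-replicate test-calibration run and a 100-seed end-to-end
ordering check on 60-protein bundles, runs in minutes. The 60-protein size
for the multi-seed check is a package choice to keep the suite fast; the
single-bundle exactness checks run at the full 300-protein composition.

Determinism is strict: `simulate_dataset()` seeds once from
`params$seed`, and `emit_dataset()` writes byte-identical files for identical
parameters.
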