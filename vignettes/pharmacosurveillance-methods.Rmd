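---
title: "Methods: prescription mapping, diversity and co-prescription networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prescription mapping, diversity and co-prescription networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsurv)
```

## The problem

Companion-animal practices record what they dispense as free text, each
practice with its own ad-hoc nomenclature ("Metacam 10ml", "1x dog annual
booster", "co-amox 250"). Surveillance at population level needs three
things on top of that raw text: a mapping into a shared drug taxonomy,
summary statistics that are honest about the clustered structure of the
data (consultations within sites, animals within practices), and metrics
that reveal *how* practices prescribe, not just how much. This vignette
describes the methods this package implements for each step, the
assumptions behind them, and the choices made where the design was
genuinely open.

## Text mapping

Mapping is a two-stage rule system over normalised text (lower case,
whitespace collapsed, dash/quote variants standardised — normalisation is
idempotent, so rules can be authored against their own output):

1. **Exclusion regexes** veto descriptions that merely *mention* a drug:
   diagnostic tests ("phenobarbitone toxicity test"), consumables ("insulin
   syringes x10"), refunds. Exclusion strictly dominates identification.
2. **Identification strings** are literal, case-insensitive substrings,
   each tied to one taxonomy entry (agent → class → family →
   authorisation). One description may hit several entries — combination
   and multivalent products are real and common, especially among
   parasiticides — and matches are de-duplicated per consultation at entry
   level, since all downstream counting is per consultation.

Two conventions resolve ambiguity the source data cannot: when one matched
pattern occurs *inside* an occurrence of a longer matched pattern, only the
longer survives ("clavulanate-amoxicillin" beats "amoxicillin",
"enrofloxacin" beats the embedded "ofloxacin"), which prevents
double-counting constituents; and unmatched, non-excluded descriptions are
retained and reported as a coverage statistic rather than treated as
errors, because unrecorded or unrecognisably described products are an
acknowledged blind spot of EHR surveillance. Exclusions are compiled at
load time so a malformed regex fails when rules are read, never during
matching.

The rule CSV format carries an optional `pf` column beyond
`kind,pattern,agent,priority`: family-level descriptor entries all share
the agent label `unresolved`, so rules targeting them (vaccine boosters,
euthanasia wording, rehydration fluids) need the family to disambiguate.

## Prescription Diversity

For one practice and one pharmaceutical family, with per-class counts
$np$ summing to $NP$:

$$PD = 1 - \frac{\sum np(np-1)}{NP(NP-1)}$$

This is the Simpson/Gini–Simpson construction applied to prescribing: the
probability that two prescriptions drawn without replacement belong to
different classes. Implementation choices:

* **$NP < 2$ is undefined**, not zero: the denominator vanishes and a
  single prescription carries no information about diversity. Undefined
  values are excluded from medians and from quintile ranking.
* **Family-only events are excluded.** Descriptions resolved only to
  family level (generic vaccine descriptors and the like) have no class,
  and PD is defined over classes within a family.
* **Ceilings.** A family with $k$ classes prescribed evenly attains
  $1 - (NP-k)/(k(NP-1))$ — 0.75 for $k=4$ and 0.88 for $k=8$ at
  $NP = 2000$ — decreasing in $NP$ toward $1 - 1/k$. Because the ceiling
  depends on $k$, PD is benchmarked between practices within one family
  rather than against a theoretical maximum, which would set practically
  unreachable targets.
* **Quintile benchmarking.** Practices are ranked separately by
  prescription frequency and PD and each ranking is cut into five
  near-equal groups. "Evenly spaced" leaves two details open, fixed here
  as: ties broken by a stable sort on practice id, and when $n \bmod 5
  \neq 0$ the earlier (lower) quintiles take the extra members. No
  minimum-event threshold is imposed before ranking beyond PD being
  defined; callers can filter on the reported $NP$ if they want one.
* Reported values use half-even rounding to two decimals
  (`report_round()`), matching the precision at which PD is conventionally
  printed.

## Frequencies and the cluster bootstrap

Rates are consultation-level "at least one" counts: the rate per 10,000
consultations for a family is $10^4 \times$ (consultations with ≥ 1 event
of that family) / (consultations in the stratum), and repeat visits count
separately. Empty strata raise an undefined-result condition rather than
returning 0 — "no data" and "never prescribed" are different findings.

Confidence intervals come from a one-stage cluster bootstrap: resample
whole clusters with replacement (the observed number of clusters,
independently within strata), recompute the statistic per replicate, take
2.5/97.5 percentiles. Percentile intervals were chosen over BCa as the
simplest method consistent with a generic "bootstrap" contract; they are
easy to swap out. The clustering the data actually exhibits lives at two
levels — consultations within sites, and animals within practices — and it
is ambiguous whether a single nested resampling scheme or separate
per-level schemes is the right reading; `prescription_frequency_ci()`
therefore runs both one-stage schemes (clusters = sites; clusters =
animals stratified by practice) and reports the wider interval, which is
conservative and makes explicit which level dominates. Known percentile
quirks are handled, not hidden: an observed statistic falling outside the
interval clamps the bounds with a warning, and a single cluster yields a
degenerate zero-width interval with a warning.

Authorisation breakdowns normalise over events whose agent resolved;
family-level events have no defined authorisation and are reported
separately as not estimable instead of being folded into the denominator.

## Co-prescription networks

Co-prescription is defined at consultation level: families prescribed
together in one booked consultation. Nodes count every prescription event;
edges count consultations, so a family prescribed twice in one
consultation adds two to its node but pairs only once. Sparsification
applies two rules in a fixed order: drop nodes below 0.5% of total
prescriptions, then — over the edges that survive the node rule — drop
edges whose weight does not *exceed* the mean surviving edge weight.
Computing the mean after node removal and reading "in excess of" as strict
are the two readings this package fixes (the alternatives are not
distinguishable from the method's description); the per-existing-edge mean
is used rather than a per-possible-pair mean. Nodes left edgeless are kept
as isolates: a family that co-prescribes with nothing (euthanasia,
canonically) is a finding.

Group detection is asynchronous label propagation: unique initial labels,
random node order, each node adopts the label with the greatest total edge
weight among its neighbours, until every label has weak-majority support.
The algorithm is order-dependent by nature, so reproducibility is imposed
from outside: a fixed seed drives the update orders, the algorithm runs
`n_runs` times (default 20), and the modal partition wins, ties going to
the earliest run. Labels travel only along edges, so disconnected
components are never merged and isolates are always singleton groups. A
class-level network can be built the same way (`consult_pf_sets(...,
level = "pc")`), but group detection is intended at family level.

## The synthetic generator

`generate_dataset()` emulates the *structure* of sentinel-network EHR
data, sized by default at desk scale: 50 practices with 1–3 sites, 5,000
animals (60/30/10% dog/cat/rabbit), consultations per animal
$1 + \mathrm{Poisson}(7)$ for ~40,000 consultations over a two-year
window, ten presenting complaints, and a population prescribing
probability of 0.65 with practice random effects (SD 0.5 on the logit) so
the cluster bootstrap has real within-practice correlation to absorb.
Prescribing consultations draw 1–3 distinct families
(probabilities 0.55/0.30/0.15) from their complaint group's block profile
— preventive (vaccine and parasiticides) for vaccination/healthy visits,
treatment (antibiotic and anti-inflammatory as hubs) otherwise, with 4% of
treatment consultations euthanasia-only — and cross-block co-prescription
leaks at rate 0.02, far below within-block rates, which is what makes the
planted three-block structure recoverable. Class choice within a family
follows a per-practice Dirichlet draw (concentration 6 over decreasing
base weights), giving each practice a known generating mix whose
Gini–Simpson value $1 - \sum p^2$ is the exact expectation of the PD
estimator and is stored as ground truth. Authorisation is drawn per event
from a 90/6/4 veterinary/human/generic mix; the bundled taxonomy gives
every class one agent per category so the realised mix is unbiased for the
configured one. Descriptions are rendered with practitioner-style noise
(casing, spacing, strengths, occasional brand synonyms) that normalisation
removes; 1% of prescriptions are rendered unmatchably ("broken") to
emulate unrecognisable records, and decoy lines (fees, diets, excluded
test/syringe/refund strings) are attached to 30% of prescribing and all
non-prescribing consultations.

What the generator does **not** emulate: realistic signalment (age, sex,
breed), temporal disease trends, species-specific prescribing profiles, a
full 26-family/274-class taxonomy, authorisation mixes that differ by
family (real parasiticides are essentially never human-authorised), or
free-text clinical narratives. Passing tests therefore demonstrate that
the analysis chain recovers known structure from realistically *shaped*
data — not that any particular real population looks like the synthetic
one.

The bundled taxonomy itself is synthetic: agent names are plausible
substances, but authorisation assignments are balanced by construction and
must not be read as a formulary.

## Validation strategy and problem sizes

Every statistic is checked against an independent oracle: PD against
exhaustive discordant-pair enumeration (all compositions to total 8,
randomised compositions to total 30); edge weights against a brute-force
double loop over 1,000 consultations; Wilcoxon p-values against full
permutation enumeration for combined samples of ten; Kendall tau against
$O(n^2)$ pair counting to $n = 50$; and our label propagation against the
igraph implementation on clear topologies. Parameter-recovery suites run
the full text pipeline: planted events are conserved exactly through
rendering and mapping; per-practice PD recovers the generating mix within
±0.05 once a practice accumulates 500 family events (checked on a denser
10-practice/6,000-animal configuration, since at the 50-practice default
no single practice reaches 500 events in one family); the authorisation
mix recovers within ±0.02; planted blocks are recovered across 20
generation seeds; and bootstrap coverage is estimated from 500 simulated
clustered datasets (25 clusters × 30 binary observations, cluster
proportions Beta(8, 4), 500 replicates each), where the 95% percentile
interval is expected to cover the true marginal proportion 90–98% of the
time — slight undercoverage at 25 clusters is a known property of the
percentile method.

## Limitations

Rule-based mapping is only as complete as its string list; coverage is
reported, not guaranteed. Consultation-level counting can overstate
frequency for products with expected repeat prescriptions (vaccines,
chronic medication). The taxonomy forces each agent into a single family
by most likely intended use, although many agents (corticosteroids, for
one) serve several. Wilcoxon p-values switch between the exact and the
tie-corrected normal path following standard practice, so tied
small-sample p-values are approximate. And the Kendall test uses the
t-approximation on $n-2$ degrees of freedom; for very small $n$ an exact
tau distribution would differ.
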