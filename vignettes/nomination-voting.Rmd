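---
title: "Methods: synthetic dilution-cultivation campaigns, POC co-occurrence analysis, and the consumer-resource voting experiments"
author: "nomvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nomination-voting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomvote)
```

## The scientific problem

A natural microbial community holds a few dominant taxa and a long tail of
rare ones. Dilution-to-extinction cultivation takes one such community,
dilutes it so strongly that each well of a 96-well plate receives only a
few hundred (or a few dozen) cells, and regrows every well under identical
conditions. Dominant taxa, being abundant, enter almost every well; rare
taxa are retained or lost at random. Each well therefore assembles from a
shared pool of competitive "candidates" plus a private, random rare
background — and the striking observation is that the identity of the most
abundant taxon after cultivation (the Top1 OTU) varies widely between
wells. `nomvote` provides the three computational pieces needed to study
this: a synthetic campaign generator, the occurrence-analysis stage, and a
consumer-resource simulator.

## The synthetic campaign generator

### What it emulates

The generator's defaults reproduce the statistical skeleton of a real
dilution-cultivation study of a wheat-rhizosphere soil community:

* a raw community of **674 OTUs** in which exactly **16 dominants** (each
  ≥ 1% relative abundance) jointly hold **68.59%** of the reads;
* three dilution factors, **1.0e-4, 0.5e-4 and 1.0e-5**, filling 3, 4 and
  4 full 96-well plates: **1,056 wells**;
* per-well sequencing depth scattered around 20,000 reads with a
  realistic tail below the **5,000-read** retention threshold (about 14%
  of wells are lost to the depth filter, leaving ~900 usable
  sub-communities);
* observed per-well richness whose median falls with dilution strength;
* steep within-well dominance hierarchies (most wells have only 1-6 OTUs
  above 1%).

### How each stage works, and why

**Raw community.** Abundances are a log-normal rank-abundance draw
(`abundance_shape` is the log-sd, default 2). The top `n_dominant` ranks
are rescaled affinely so each sits strictly above the 1% threshold and
their sum equals `dominant_total_share` exactly; the remaining taxa share
the rest, with any straggler capped just below the threshold and its
surplus pushed down the tail. This keeps the few-dominants/long-tail shape
with just two knobs. A spec whose dominants cannot all clear the threshold
(or whose tail cannot stay below it — e.g. two taxa with a 90%/10% split)
is rejected as infeasible rather than silently adjusted. Taxa below
`detection_floor` (default 2e-5, i.e. under one read in a ~50,000-read
census) are flagged *undetected*: they model the extremely rare members a
raw census misses but cultivation can retrieve — the "appeared" pool.

**Inoculation.** Every taxon enters every well as an independent Poisson
count with mean `inoculum_cells × relative abundance`, the standard
stochastic model of dilution-to-extinction: occurrence in a diluted subset
depends only on initial abundance. `inoculum_cells` defaults to
`5e6 × dilution_factor` (500, 250, 50 cells per well), chosen once so that
observed richness lands in the tens per well and declines across the three
factors.

**Cultivation.** The default `"lottery"` mode draws each present taxon a
log-normal competitive fitness and sets its final share proportional to
`inoculum count × fitness`. A symmetric small-concentration Dirichlet was
considered and rejected: it cannot produce a steep dominance hierarchy and
a fat tail of low-abundance survivors at the same time, whereas the
log-normal fitness lottery does. `lottery_concentration` is the fitness
log-sd; its default of 5 balances the two emulation targets (roughly
three-quarters of wells end with 1-6 dominant OTUs, and median observed
richness stays in the tens: about 32/25/13 across the three factors,
monotone like the real 59/33/24 though smaller in level — the lottery
makes low-fitness taxa vanish from the sequencer slightly faster than real
cultivation does). The alternative `"crm"` mode assigns every taxon
consumer-resource traits once per campaign and integrates the community
ODE per well; it is mechanistically coherent but ~100× slower, so the
lottery is the default.

**Sequencing.** Depth per well is negative-binomial (`depth_mean` 20,000,
size 1.5), giving P(depth < 5,000) ≈ 0.139 — exercising the depth filter
at about the rate seen in practice. Reads are a multinomial draw of that
depth from the final shares; empty wells yield zero-read samples. Well IDs
follow `P01_A1` (plate, row, column) for traceability.

All randomness flows from explicit seeds; `simulate_campaign()` spawns
per-stage child seeds from one master seed, so a single integer reproduces
an entire campaign.

### What it does not emulate

No taxonomy, phylogeny, PCR/chimera artefacts, OTU clustering, or fitting
to any real sequencing run. Passing tests on synthetic campaigns show the
analysis stage is internally correct and that its qualitative behaviour
(depth-filter losses, richness-vs-dilution, exclusion-dominated POC
spectra) matches the study conditions — not that the generator reproduces
any particular real dataset.

## The occurrence-analysis stage

The conventions, each fixed deliberately:

* **Depth filter**: samples with *fewer than* `min_reads` (default 5,000)
  total reads are removed — strictly fewer, so a 5,000-read sample stays.
* **Presence** means ≥ 1 read in a retained sample; there is no per-OTU
  count floor.
* **Dominance** is *inclusive*: relative abundance ≥ 1.0% is dominant.
  The threshold is a cut-point and the boundary case is conventionally in.
* **Turnover**: each occurrence crosses raw status with sub-community
  status into D-to-D, R-to-D, D-to-R or R-to-R; OTUs undetected in the raw
  community ("appeared") count as raw-rare. A sample is a *D-to-D
  sub-community* iff its D-to-D abundance share strictly exceeds its
  R-to-D share; ties go to R-to-D (arbitrary but fixed; ties have measure
  zero on real data).
* **Groups A-D** partition the OTU universe by dominant-occurrence count:
  ≥ 10, 1-9, present-but-never-dominant, absent-from-all-wells.
* **Pair universe**: OTUs occurring in *strictly more than*
  `min_occurrence` (default 10) sub-communities; `n` OTUs give
  `n (n − 1)` ordered pairs (169 OTUs give 28,392).
* **POC**: for focal occurrence count `X` and co-occurrence `XYcoe`,
  `POC = XYcoe / (X − XYcoe)`; `Inf` when the counts coincide, 0 when
  there is no co-occurrence. Values are kept at full precision and also
  rounded to two decimals for display. Because the directed statistic is
  asymmetric and verbal phrases like "the POC for A to B" are ambiguous
  about which occurrence count sits in the denominator, the API is always
  parameterised by the *focal* OTU (the denominator's `X`) and reports
  both directions of a pair explicitly.
* **Top-N ranking**: shares sorted descending, ties broken by OTU ID —
  determinism for testing.

The POC implementation is verified against a brute-force oracle that
recounts occurrences and co-occurrences sample by sample for every ordered
pair of random presence/absence matrices, with exact equality required.

## The consumer-resource model

Biomasses and resources follow

$$\frac{dN_i}{dt} = N_i\Big(g_i \sum_j U_{ij} R_j - m\Big), \qquad
  \frac{dR_j}{dt} = -R_j \sum_i g_i N_i U_{ij}.$$

Maintenance is **per-capita** (inside the bracket): the printed form of
such equations is often typographically ambiguous, but per-capita loss is
the standard consumer-resource convention, keeps `N = 0` absorbing, and
yields the exact identity `d(ΣN + ΣR)/dt = 0` at `m = 0` that the tests
use as a conservation oracle. With `m > 0` the total is strictly
dissipative, and with no usable resources each species decays as
`N(0) e^{-mt}` — a closed form the solver is checked against at relative
error < 1e-3.

Numerical choices: `deSolve::lsoda` (adaptive, stiff-capable) with
`rtol = 1e-8`, `atol = 1e-10` — tight enough that the `m = 0` conservation
drift stays below 1e-6 relative over 100 time units; states are clamped at
zero inside the right-hand side and after integration; species ending
below `extinction_floor` (1e-9 of total initial biomass) are reported
extinct so round-off survivors never enter relative abundances.

### Trait strata

The four functional groups cross growth with metabolic flexibility, on
deliberately disjoint ranges so group identity is unambiguous:

| stratum | high | low |
|---|---|---|
| growth rate `g` | U(0.8, 1.2) | U(0.2, 0.4) |
| breadth (fraction of resources) | U(0.6, 0.9) | U(0.1, 0.3), floor 1 |

Uptake coefficients are U(0.5, 1.5) on usable resources. Total initial
resource is fixed at 10 regardless of how many resource types it is split
over, so resource-richness levels are comparable; initial biomass is 1.

### The three experiments

**Nomination (Step 1).** Fresh 80-species communities (20 per group),
equal initial biomass, at 1, 5, 10 and 20 resource types, 100 replicates
each: the HH group's mean share is the largest and grows with resource
complexity — competitive traits nominate.

**Voting (Step 2).** One fixed pool of 20 HH candidates holds 95% of
initial biomass; each replicate adds 60 random rare species (HL/LH/LL,
jointly 5%) in a 10-resource environment. Here a genuine design question
arises: if candidates are drawn freely from the HH strata, one candidate's
intrinsic edge exceeds anything a 5%-biomass background can flip, and the
same species wins every replicate — the experiment degenerates. The
experiment's premise, however, is *uniform intrinsic competitiveness* of
the candidates. The package therefore equalises them exactly: identical
growth rate (1.0), identical breadth (70% of resources), unit uptake, and
resource subsets assigned by a balanced cyclic design (every resource
supports the same number of candidates; all subsets distinct; the layout
seeded). Absent rare taxa, all candidates then tie *exactly*; whatever
decides the winner is the rare background — the voting mechanism in its
pure form. Under this design tens of distinct candidates take Top1 across
100 replicates.

**Structured rares (Step 3).** Each structured rare species picks one of
the `targeted` candidates (default the first 10) and draws its usable
resources with probability `bias = 0.9` from that candidate's resource
set, else uniformly from the rest. Targeting is per-candidate rather than
against the pooled union of targeted resource sets because with ten
high-breadth candidates over ten resources that union is every resource —
a union-level bias would collapse the structured scenario into the random
one. The per-candidate form still elevates union membership, concentrates
interference on the targeted profiles, and lets the shielded candidates
out-win the targeted ones; `targeted = 0` applies no bias and reproduces
the random scenario exactly under the same seed. Both scenarios run on the
same per-replicate seeds (paired comparison), summarised by the
total-variation distance between their Top1 frequency vectors.

```{r voting-demo, eval = FALSE}
vote <- run_voting(replicates = 100, seed = 1)
table(vote$top1)                      # many distinct winners
st3 <- run_structured(replicates = 100, seed = 1)
st3$tv                                # Top1 distribution shift
c(shielded = st3$shielded_wins, targeted = st3$targeted_wins)
```

## Problem sizes used by the test suite

The suite exercises the full 674-OTU × 1,056-well campaign once for the
empirical invariants, the POC oracle on 200 random 20 × 50 matrices,
conservation on 20 random communities, the nomination experiment at 25
replicates per resource level, and the voting/structured experiments at
100 replicates — sizes at which the stochastic contrasts of interest are
well outside Monte-Carlo noise while a full run stays in the minutes.

## Known limitations

* The lottery cultivation mode reproduces hierarchy steepness and
  richness monotonicity but compresses observed richness relative to real
  cultivation; the `crm` mode is mechanistic but slow.
* POC inherits the usual caveat of occurrence-based statistics: dilution
  stochasticity contributes absences that are not ecological exclusion,
  so exclusion-type categories are upper bounds on true antagonism.
* The ODE model has no cross-feeding, spatial structure, or demographic
  noise; rare-background "voting" here operates purely through shared
  resource depletion.
* Candidate equalisation in Steps 2-3 is an idealisation: real candidate
  pools are only approximately equivalent, so real Top1 distributions mix
  intrinsic and background effects.
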