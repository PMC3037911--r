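---
title: "Topological mapping of NM-anchored DNA loops: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological mapping of NM-anchored DNA loops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmapr)
library(dplyr)
```

## The assay in brief

In interphase nuclei, DNA is organised as supercoiled loops anchored to the
nuclear matrix (NM) at loop anchorage regions (LARs). After high-salt lysis,
the residual "nucleoid" retains naked, topologically constrained loops whose
local resistance to a limited concentration of DNase I grows with proximity
to the NM, for two reasons: the supercoiling gradient that runs from loop
tip to anchor, and steric shielding by NM proteins. Digesting a nucleoid
population for increasing times therefore strips loop DNA from the outside
in, and the bulk kinetics of the % of DNA still NM-bound partitions the
loops into four operational *topological zones*: distal (lost in the fast
first phase), proximal, very close, and NM-embedded (the nuclease-resistant
residual). Scoring a specific PCR amplicon as present/absent in partially
digested samples taken at each zone's representative time locates that
sequence relative to the NM; repeating the mapping in quiescent (G0),
synchronously replicating (24 h after partial hepatectomy, PHx-24) and
re-quiescent (PHx-7D) rat hepatocytes tracks how loop DNA moves during
replication in vivo.

`loopmapr` implements every computational layer of this assay: a generative
simulator of the digestion experiment, kinetic-phase segmentation, zone
assignment from call matrices, cross-condition shift analysis, and
generative predictors for three candidate replication mechanisms.

## Loop architecture

A `loop_architecture` holds the region length, the ordered, non-overlapping
loops (anchor/tip coordinates, 0-based half-open, strand-agnostic) and the
amplicons. The relative NM distance of a position is its arc distance to the
nearest anchor divided by the anchor-to-tip arc span: 0 at a LAR, 1 at the
tip, piecewise linear in between.

The built-in albumin-family fixture covers the 162 kbp rat chromosome 14
region organised into five structural loops, with fifteen amplicons (a–o,
each ≤ 547 bp) spaced every 10 kb. The source material does not print the
LAR coordinates (they come from a companion topological study), so the
default fixture places five *equal-span* loops and accepts an override; this
keeps the fixture honest about what is actually known. With equal symmetric
loops the NM-distance distribution of loop DNA is uniform, which also makes
the zone-quantile mapping (below) transparent.

```{r arch}
arch <- albumin_architecture()
nm_distance(arch)
```

## The nucleoid digestion simulator

The simulator is the package's synthetic-data generator: it produces bulk
digestion curves and per-amplicon survival with the statistical structure
the analysis assumes, under the study conditions.

**Survival law.** A DNA segment with cleavage hazard $h$ would survive as
$e^{-ht}$ if the hazard were constant, but every single-strand nick becomes
a point of progressive unwinding, eroding the supercoiling that protects the
rest of the population. We model this as a hazard inflated by the cumulative
cleaved fraction, $h(1 + \alpha C(t))$, giving the closed form

$$S(t) = \frac{(1+\alpha)\,e^{-(1+\alpha) h t}}{1 + \alpha e^{-(1+\alpha) h t}},$$

which reduces to the exponential at $\alpha = 0$ (that limit is the
independent oracle used in the tests). Per-nucleoid cleavage times are drawn
by inverse-transform sampling from $S$, so every simulated fraction is an
unbiased binomial estimate of the law.

**Distance dependence.** The hazard at relative NM distance $d$ is
$h(d) = r\,m\,e^{-k(1-d)}$ with base rate $r$ (`dnase_rate`), condition
multiplier $m$ and `supercoil_steepness` $k$; sequences with $d$ below the
embedding cutoff (default 0.05) instead use the strongly attenuated embedded
hazard $r\,m\,\rho$ (`embedded_resistance` $\rho$, no acceleration — embedded
DNA is shielded, not supercoil-protected). One uniform draw per nucleoid is
shared across amplicons (a nucleoid's overall digestion progress), so the
ordering "farther from the NM ⇒ pointwise smaller survival" holds exactly
for every seed, not just in expectation.

**Calibration.** Bulk curves are a zone-mass mixture: each nucleoid carries
`zone_mass` fractions of its DNA in the four zones, cleaved at the hazards
of representative distances (0.80, 0.45, 0.15 for distal/proximal/very
close). The default parameters ($r = 0.46\ \mathrm{min}^{-1}$, $k = 4$,
$\alpha = 3$, $\rho = 0.0019$) were fixed once, by closed-form algebra
against the published G0 phase fractions — not by fitting simulation output:
with G0 masses (0.60, 0.10, 0.10, 0.20) they give ~60% of DNA removed by
5 min, ~10% more by 15 min, ~10% more by 60 min, ~20% residual. The
`caption_slopes` calibration instead derives zone masses from the published
per-phase slopes (49/17/12.15/21.85% for G0). The two are arithmetically
inconsistent in the source (−9.80 %/min over 5 min removes 49%, not 60%);
both are shipped, neither is "corrected", and the percentage calibration is
the default because those percentages define the zone masses the whole
analysis uses.

**Condition profiles.**

* `G0`: masses (0.60, 0.10, 0.10, 0.20), $m = 1$.
* `PHx24`: embedded mass halved to 0.10 (replication forks expose
  single-stranded DNA inside the NM), the freed mass redistributed over the
  loop zones; $m = 1.3$, chosen in closed form so ~70% of DNA is removed by
  5 min (≈30% remains) and the 60-min residual is about half the G0 value;
  and `loop_contraction = 0.5`: the *effective* NM distance of every
  amplicon is halved. The contraction is the simulator's expression of the
  reel-in configuration at the average S-phase snapshot — it is what makes
  individual templates *more* persistent at PHx-24 (they sit closer to the
  NM) even though bulk digestion is faster. Without it, a faster global
  hazard alone would push simulated zone ordinals *away* from the NM,
  contradicting the observed shift pattern.
* `PHx7D`: identical to `G0` — regeneration restores the original topology.

**Detection.** An amplicon is "+" at a zone's sampling time if its intact
fraction is at least `detection_threshold` (default 0.1; the assay's
"non-amplifiable level" is not quantified, so the threshold is exposed in
the config). Raising the template amount `fold`-fold is equivalent to
dividing the threshold by `fold` (`boost_template()`): assignments can only
move closer to the NM, and a six-fold boost uncovers template in the
NM-embedded fraction, as in the high-template control experiment.

**What the simulator does and does not emulate.** It reproduces the
three-phase-plus-plateau kinetics, condition-specific zone masses, the
distance-ordered survival of amplicons, thresholded presence/absence calls
and template boosting. It does not model sequence-specific DNase I
preference, replicate-animal variability (the tables' asterisks), PCR
chemistry, or explicit single-strand cleavage at forks (absorbed into the
PHx-24 parameters). Passing tests on simulated data therefore validate the
analysis pipeline's logic and calibration, not wet-lab variability.

```{r sim}
cfg <- simulation_config(n_nucleoids = 2000, seed = 1L)
g0 <- simulate_bulk_digestion(condition_profile("G0"), cfg)
tidy(segment_phases(g0))
```

## Kinetic segmentation and the zone schedule

`segment_phases()` fits an ordinary least-squares slope inside each
breakpoint window. Windows default to (0, 5, 15, 30, 60) min — the published
analysis fixes them — and are closed on both ends, so a boundary point
belongs to both adjacent windows, matching how the published windows are
stated. A data-driven changepoint search (`find_breakpoints()`, exhaustive
SSE minimisation over the sampled times) is provided but off by default. On
exact piecewise-linear input the fit recovers the generating slopes to
machine precision, which is the oracle test for the fitter. Off-grid
queries use linear interpolation — the simplest defensible choice at this
sampling density.

`derive_zone_schedule()` maps window $k$ to zone ordinal $k$ (distal = 1 …
embedded = 4; larger = closer to the NM) with the window's right endpoint as
the representative sampling time, i.e. (5, 15, 30, 60) min by default.
Ordinal 0 ("hypersensitive") is reserved for sequences already gone at the
distal sampling time.

## Zone assignment and shift analysis

`assign_zone()` takes a row of calls over (C, D, P, VC, E) and returns the
index of the deepest column scored "+" (C, the undigested control, must be
"+" and does not count). Design choices, each of which matters for the
worked examples:

* Asterisked entries ("+\*", "−\*") are replicate-variability annotations;
  the sign is used as printed and the flag is retained. The "+/−" entries of
  the boosted-template table (signal drifting between experiments) are
  parsed as "−" with the flag — a drifting signal is not a reproducible
  detection. These conventions exactly reproduce the published counts,
  which are the only available validation.
* A "+" after a "−" never occurs in the encoded tables; for robustness the
  rightmost "+" wins and the row is flagged non-monotone with a warning.
* "Closer to the NM" is strictly ordinal (Δ ≥ 1); and a sequence whose
  PHx-7D ordinal is 0 when its control was 1 has *not* returned — this
  distinction is required to obtain the published count of 8 returned
  sequences.

`shift_analysis()` and `classify_trajectories()` quantify the movement:
with the sample-specific calibration table, 11 of 15 albumin-region
amplicons shift exactly one zone closer at PHx-24, 8 of those return at
PHx-7D, a and m stay proximal, c and g stay distal; all four unrelated
genes shift closer and return. `replay_mapping_study()` recomputes all of
these from the shipped fixtures and treats any deviation as a hard error,
making the published counts the pipeline's regression gate.

```{r replay}
rep <- replay_mapping_study()
rep$validation
```

## Replication-mechanism models

Three generative predictors translate a quiescent baseline assignment and an
S-phase progress $s \in [0,1]$ (fraction of loop DNA replicated) into
predicted zones:

* **Tracking** — the polymerase moves along a static template: prediction =
  baseline at every $s$.
* **Tip reel-in** — the origin at the loop tip binds the NM in late G1,
  halving each loop: for $s > 0$ distances are recomputed on the half-loops
  (nearest of the anchors and the tip-anchor, normalised by the quarter
  span). Anchoring a tip can only bring DNA closer, so predictions are
  floored at the baseline ordinal. LAR-adjacent DNA replicates last under
  this model.
* **LAR reel-in** — origins sit by the LARs; fixed forks on the NM consume
  the template symmetrically from both anchors. At progress $s$, sequences
  in the outer $sL/2$ of each side are replicated: their daughter duplexes
  have been extruded, restoring the baseline position (an alternative
  "stay embedded" variant is available for sensitivity analysis). The rest
  are mapped by their arc distance to the nearest fork — unreplicated DNA
  is pulled inward.

Distances become ordinals through **zone-mass quantile thresholds**: zones
are operationally defined by how much DNA they contain, so the embedded zone
is the closest `zone_mass["embedded"]` fraction of loop DNA, and so on.
Thresholds are computed once from the quiescent architecture's distance
distribution and applied to each model's effective distances, keeping model
predictions commensurate with observed ordinals. Because an observed
baseline need not coincide with the threshold map of raw distances, both
reel-in models return the baseline exactly at $s = 0$ (and the LAR model
also at $s = 1$), honouring the constraint that they coincide with tracking
before any replication has occurred.

`discriminate()` scores each model's concordance (fraction of amplicons with
matching ordinals) against an observed S-phase assignment over a grid of
$s$ values — 21 evenly spaced points by default, since the PHx-24 snapshot
is an unknown population average over S phase — and reports each model's
best score and the winner (ties broken in model order and flagged). On the
sample-specific PHx-24 observation with the albumin fixture, tracking can
explain only the four fixed amplicons (4/15) while the LAR reel-in reaches
7/15 around $s \approx 0.45$; no quantitative concordance is printed in the
source, so this verdict is validated as an ordering property, not against a
reference score.

```{r models}
g0z <- assign_zones(filter(mapping_fixture("table3"), condition == "G0"))
phxz <- assign_zones(filter(mapping_fixture("table3"), condition == "PHx24"))
discriminate(arch, g0z, phxz)
```

## Numerical choices and problem sizes

* Population size defaults to 2000 nucleoids: the binomial standard error
  of any simulated fraction is then below 1.2 percentage points, an order
  of magnitude inside the ±5 pp calibration bands, and a full
  three-condition end-to-end run takes seconds. Tests use 200–4000
  depending on how tight the comparison is.
* All randomness flows from the single integer `seed` in
  `simulation_config()`; a fixed seed fixes every output bit for bit.
  `simulate_end_to_end()` derives per-condition seeds as
  `seed + 1000 * (condition index - 1)` so conditions are independent but
  the bundle is reproducible.
* Degenerate inputs: `n_nucleoids = 1` runs and produces well-formed (if
  noisy) outputs; `dnase_rate = 0` keeps everything bound; empty call
  matrices assign to an empty tibble; ties at a zone threshold resolve to
  the deeper zone (`d <= d_max`).
* Quantile thresholds use a 20,000-point arc-length grid; for the
  equal-loop fixture the resulting thresholds are exact to ~1e-4.

## Known limitations

* The fixture's loop boundaries are a declared idealisation (equal spans);
  conclusions that depend on exact LAR positions should re-run with
  measured coordinates via the `loops` override.
* Replicate-level variability (the asterisks) is carried as a flag but not
  modelled stochastically; the source never quantifies it.
* The PHx-24 `loop_contraction` is a single population-average number, not
  an origin-timing model; fork firing heterogeneity across the population
  is out of scope.
* Model discrimination is a concordance ordering over a 1-D progress grid;
  it is not a likelihood and carries no significance statement (the source
  reports none).
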