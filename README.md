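# loopmapr

Topological mapping of nuclear-matrix-anchored DNA loops from DNase I
digestion kinetics.

In metazoan interphase nuclei, DNA is organised as supercoiled loops
anchored to the nuclear matrix (NM). After high-salt lysis the residual
"nucleoid" keeps its naked loops topologically constrained, and their
resistance to a limited concentration of DNase I grows with proximity to
the NM (supercoiling gradient plus steric shielding). Timed partial
digestion therefore sorts loop DNA into four operational **topological
zones** — distal, proximal, very close and NM-embedded — and scoring a PCR
amplicon as present (+) or absent (−) in samples taken at each zone's
representative time locates that sequence relative to the NM. Comparing
maps between quiescent hepatocytes (G0), hepatocytes at the peak of DNA
synthesis after partial hepatectomy (PHx-24) and re-quiescent hepatocytes
(PHx-7D) asks how loop DNA moves during replication in vivo, and which
replication mechanism — a tracking polymerase, or template reeled through
fixed NM-bound replication factories — explains the movement.

`loopmapr` is for computational biologists who want this whole analysis as
tested, composable R functions:

* **Simulator** (`condition_profile()`, `simulation_config()`,
  `simulate_bulk_digestion()`, `simulate_amplicon_survival()`,
  `call_matrix()`, `boost_template()`): stochastic digestion of a nucleoid
  population. Per-zone survival follows the closed form
  `S(t) = (1+α) e^{-(1+α)ht} / (1 + α e^{-(1+α)ht})`, an exponential law
  whose hazard `h(d) = r·m·exp(-k(1-d))` rises with relative NM distance
  `d` and inflates with cumulative cleavage (each nick unwinds
  supercoils); bulk curves mix zones by DNA-mass fractions.
* **Kinetics** (`segment_phases()`, `derive_zone_schedule()`,
  `compare_conditions()`): OLS slopes per fixed (0, 5, 15, 30, 60) min
  window, zone schedules, and cross-condition contrasts.
* **Mapping** (`assign_zone()`, `assign_zones()`, `shift_analysis()`,
  `classify_trajectories()`): zone ordinal = deepest "+" column;
  per-amplicon Δzone between conditions; trajectory classes
  (fixed proximal/distal, shifted-and-returned, ...).
* **Replication models** (`predict_tracking()`, `predict_tip_reel_in()`,
  `predict_lar_reel_in()`, `discriminate()`): generative zone predictors
  at S-phase progress `s`, scored by concordance with the observed map.
* **Pipelines** (`replay_mapping_study()`, `simulate_end_to_end()`): the
  encoded-table replay with hard validation of the published counts, and a
  fully synthetic digestion-to-shift run.

Encoded call matrices for the 162 kbp rat albumin-family region (15
amplicons, five loops) and four unrelated genes ship in
`inst/extdata/`; results are tibbles with `tidy()`/`glance()`/`autoplot()`
methods throughout.

## Worked example

Simulate quiescent-cell digestion and segment the kinetic phases:

```r
library(loopmapr)
library(dplyr)

cfg <- simulation_config(seed = 1L)              # 2000 nucleoids
g0  <- simulate_bulk_digestion(condition_profile("G0"), cfg)
tidy(segment_phases(g0))
#> # A tibble: 4 × 6
#>   phase t_start t_end   slope intercept n_points
#>   <int>   <dbl> <dbl>   <dbl>     <dbl>    <int>
#> 1     1       0     5 -12.4        96.5        6
#> 2     2       5    15  -1.05       43.4        5
#> 3     3      15    30  -0.335      33.6        4
#> 4     4      30    60  -0.132      27.3        4
```

The steep first phase strips ~60% of the DNA (the distal zone) in five
minutes; successive phases flatten as digestion approaches the NM, and
~20% stays bound — the NM-embedded fraction.

Map the albumin-region amplicons from the encoded sample-specific call
table and quantify movement at the peak of DNA synthesis:

```r
fx   <- mapping_fixture("table3")
g0z  <- assign_zones(filter(fx, condition == "G0"))
phxz <- assign_zones(filter(fx, condition == "PHx24"))
glance(shift_analysis(g0z, phxz))
#> # A tibble: 1 × 6
#>       n shifted_closer_by_one shifted_closer_total fixed moved_away mean_delta
#>   <int>                 <int>                <int> <int>      <int>      <dbl>
#> 1    15                    11                   11     4          0      0.733
```

Eleven of the fifteen sequences sit exactly one zone closer to the NM in
replicating cells; none moves away. Which replication mechanism explains
that pattern?

```r
discriminate(albumin_architecture(), g0z, phxz)
#> <model_verdict> winner: lar_reel_in
#> # A tibble: 3 × 3
#>   model       s_best concordance_max
#>   <chr>        <dbl>           <dbl>
#> 1 tracking      0              0.267
#> 2 tip_reel_in   0.05           0.333
#> 3 lar_reel_in   0.45           0.467
```

A tracking polymerase (static template) can only explain the four fixed
amplicons (4/15); reeling the template through anchor-adjacent fixed forks
explains 7/15 at mid-S-phase progress, winning the comparison — the
sequential, reel-in movement of looped DNA towards the NM.

See `vignettes/topological-mapping.Rmd` for the models, calibrations and
design decisions in full.

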