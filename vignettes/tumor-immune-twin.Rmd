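---
title: "From measured cell tables to tumor–immune dynamics: the spatabm model and its choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From measured cell tables to tumor-immune dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why initialization is the experiment

A spatial agent-based model (ABM) of a tissue needs a starting
configuration, and for short simulated horizons (days) that configuration
never stops mattering: it decides who is in contact with whom, where
division has room to act, and where immune cells first meet their targets.
`spatabm` treats initialization as the independent variable. Its three
strategies — well-mixed, structured, and spatial-informed — share one cell
census and one parameter set, so every difference in the outcome is
attributable to spatial arrangement alone.

The spatial-informed strategy is deliberately literal: each model cell is
placed at the measured coordinates of a real cell, with no jitter and no
resampling (`init_spatial_informed()` with the identity transform is
bit-exact). Cells that share a spot centroid start coincident; the first
mechanics steps push them apart along a deterministic pseudo-random axis
keyed on the pair's ids, which keeps runs reproducible. We chose not to
jitter at input time because any jitter scale would be an arbitrary prior
on the assay's spatial error, and the mechanics relaxation achieves the
same separation without one.

## The model

Agents are disc-shaped 2D cells with radius 8 µm. Two clocks run:

* **mechanics**, every `dt_mech = 0.5` min: each overlapping pair
  (distance `d` below the radii sum `R`) displaces both members away from
  each other by `dt_mech · s · (1 − d/R)²` with `s = 10` µm/min. This is
  the standard overdamped quadratic-overlap repulsion of off-lattice cell
  frameworks; there is no adhesion term, so gaps opened by cell death are
  refilled by division rather than by tissue recoil.
* **phenotype**, every `dt_phen = 6` min, in a fixed order — migration,
  division/death, attack — chosen once so that trajectories are exactly
  reproducible; the model statement itself does not privilege any order.

Type behavior follows the biology the model is meant to isolate: only
cancer cells divide (rate 0.03/h) or apoptose (0.004/h); CD8+ T cells
migrate and kill; healthy epithelial cells are inert and serve as a
conservation check (their count must never change — the test suite
asserts this on every snapshot of every scenario).

**Migration** is a persistent random walk: a non-attacking CD8 cell
redraws its heading uniformly with probability `dt_phen / τ` (`τ = 10`
min) and advances `v · dt_phen` (`v = 2` µm/min). We chose an undirected
walk over chemotaxis because the model contains no diffusible field to
climb; the test suite verifies the walk's mean squared displacement
against the discrete closed form
`MSD(n) = ℓ² [n + 2 Σ_k (n − k) q^k]`, `q = 1 − dt/τ`.

**Division** is contact-inhibited: a cancer cell divides only while at
most `m = 5` neighbors (any type) lie within `1.25 (r_i + r_j)` = 20 µm.
The threshold is the model's carrying-capacity dial, discussed below.
Daughters appear one radius away at a uniform angle.

**Attack** is a timed, exclusive pair bond: a free CD8 cell with at least
one untargeted cancer cell in contact (same 20 µm criterion) engages with
probability `attack_rate · dt_phen`, choosing the nearest eligible target
(ties to the lowest agent id — an arbitrary but stated and tested rule).
Both cells freeze for 30 min; then the target dies with probability 0.8
and the pair dissolves either way. One attacker per target and one target
per attacker; whether real CD8–tumor conjugates are exclusive is not
settled, and exclusivity is the variant with the fewest free parameters.

All per-step probabilities are linear (`rate × dt`); configurations where
any `rate × dt_phen ≥ 1` are rejected at load time rather than silently
saturated mid-run. Domain walls reflect, so cells are conserved and no
loss term is introduced at the boundary.

## Parameters, units, and where they come from

| parameter | value | units | role |
|---|---|---|---|
| cancer division rate | 0.03 | 1/h | ~23 h minimum cycle, epithelial scale |
| cancer apoptosis rate | 0.004 | 1/h | slow background turnover |
| `max_neighbors_for_division` | 5 | count | pins carrying capacity at confluence |
| CD8 speed / persistence | 2 / 10 | µm/min / min | motile T-cell scale |
| attack rate | 3×10⁻⁴ | 1/min | calibrated, see below |
| attack duration / kill prob. | 30 / 0.8 | min / – | granzyme-kill timescale |
| contact scale | 1.25 | – | contact = 20 µm for 8 µm radii |
| repulsion strength | 10 | µm/min | relaxes overlap in ~minutes |
| `dt_mech` / `dt_phen` | 0.5 / 6 | min | mechanics ≪ phenotype timescale |

Two of these deserve their own account, because they were set by
calibration against the intended qualitative behavior of the well-mixed
scenario (early decline, then a plateau near 90% of the initial cancer
count) rather than taken from first principles:

**The contact-inhibition threshold (`m = 5`).** With threshold 20 µm, a
confluent hexagonal packing at 16 µm spacing gives each cell exactly 6
neighbors. Setting `m = 6` therefore lets division continue *past*
confluence: the tissue compresses until second-shell neighbors enter
range (~11.5 µm spacing), and between those two densities lies a wide
dead zone in which nothing divides yet killing proceeds — population
dynamics there are knife-edged and collapse or explode. `m = 5` stops
division exactly at confluence, so any vacancy created by death
immediately re-enables its neighbors, giving the steep, fast density
feedback that makes the observed plateau an attractor instead of a
coincidence.

**The attack rate (3×10⁻⁴/min).** At the plateau, immune kills must
balance the division surplus that confluence allows (a few cells per
hour per thousand). Per contact-hour this is a small hazard; larger
values push the sustained kill flux above the maximum division refill
rate (`0.03/h` per eligible cell) and drive the tumor to extinction, as
sweep runs during calibration showed. The rate sets how fast the initial
decline happens; the plateau *level* is set by geometry (below).

**Scenario geometry.** The well-mixed disc (radius 335 µm) nearly fills
its domain (`[−340, 340]²` µm), so the mixed tissue starts at carrying
capacity: ~2900 cells at near-confluent density with no room to expand.
Killing and apoptosis trim the excess, division refills to capacity, and
the cancer share equilibrates near 90% of its initial count. The
structured scenario (epithelial disc of 400 µm, immune annulus 400–520
µm) and the spatial-informed scenario sit in a `[−800, 800]²` µm domain
with room to grow, which is exactly why they show net tumor growth while
the well-mixed scenario does not: the comparison isolates how the
*arrangement and confinement* of the same census changes the outcome.
With the shipped seeds (1–3) the acceptance suite measures a well-mixed
plateau of ~92% of the initial count, roughly threefold structured
growth with ~98% of endpoint cancer cells in components larger than 100
cells, and intermediate spatial-informed growth.

## Spatial readouts

The cross-pair correlation function is the uncorrected estimator
`g_k = (1/N_C) Σ_i n_i(k) / (λ_T a_k)` on 10 µm annuli from 0–200 µm:
target counts around each center, normalized by the globally estimated
target intensity and averaged over centers. We deliberately ship no
boundary edge-correction — the estimator stays a pure counting statistic,
byte-reproducible and cheap — and instead document the consequence: bins
whose outer radius is comparable to a center's distance from the domain
wall are biased low. The test suite verifies the complete-spatial-
randomness null (`g ≈ 1`) with centers kept one maximal bin radius away
from the walls, plus two exact invariances (coordinate rescaling;
duplication of every target).

Component structure uses the contact graph (`d ≤ 1.25 (r_i + r_j)`),
restricted to the cancer-induced subgraph before extracting connected
components — the cluster notion is "contiguous cancer tissue", not
"cancer cells reachable through healthy bridges"; the full-graph
convention remains available (`induced = FALSE`). The component CDF is
cell-weighted, `F(s)` = fraction of cancer cells in components of size
≤ `s`. Replicates are aggregated by evaluating each CDF on the union of
observed sizes with right-continuous step interpolation (a CDF is a step
function; linear interpolation would invent mass between observed sizes)
and reporting pointwise mean ± 1 sample SD (`n − 1`; SD 0 for a single
replicate).

## The synthetic tissue generator

`generate_pdac_like_sample()` emulates the salient architecture of an
immune-infiltrated pancreatic ductal adenocarcinoma sample: a malignant
core (jittered triangular lattice at 16 µm spacing — near-confluent
epithelium, so spatial-informed runs begin at tissue density), a healthy
ring outside it, and CD8 cells at radius `Normal(core_radius, 50 µm)` —
immune density peaked at the malignant border. Default census: 1500
cancer, 800 healthy, 600 CD8; core radius 350 µm. These numbers are
synthetic stand-ins chosen to keep the full study at ~3000 agents; they
are not measurements. What the generator does *not* emulate: expression
data of any kind, spot-level mixing, irregular tumor boundaries,
multi-focal lesions, stromal compartments, or assay noise. Tests passing
on this sample therefore demonstrate that the pipeline is correct and
that border infiltration dynamics appear — not that the model reproduces
any particular patient.

## Numerical and degenerate-input choices

* Exact per-type counts at initialization (no multinomial rounding);
  abundance-based placement for non-spatial tables uses largest-remainder
  rounding with lexicographic tie-break, so totals are exact and
  deterministic.
* Disc/annulus sampling by inverse-CDF radial transforms
  (`r = R√u`; `r = √(r_in² + u(r_out² − r_in²))`), area-uniform by
  construction and KS-tested at n = 10⁴.
* One shared RNG stream per replicate (R's global stream; the compiled
  engine draws through the same generator), agents updated in id order:
  a seed fully determines a run, across platforms, at the level of
  written CSV output.
* Coincident cells repel along a hash-derived axis; exactly-touching
  cells (`d = R`) feel zero force; agents locked in an attack exert
  repulsion but do not move.
* Zero-target PCFs return `g = 0` with a flag and a warning; snapshots
  with no center cells yield masked (NA) heat-map columns; empty
  component lists yield an empty, flagged CDF.

## Problem sizes

The shipped study is 3 scenarios × 3 replicates × 5 simulated days at
~2900–5000 agents (a few tens of seconds per run with the compiled
engine). Unit tests run the same machinery at tens-to-hundreds of agents
and minutes-to-hours of simulated time; the Monte-Carlo checks use
10⁴–10⁵ draws and 5–20 replicate patterns. These sizes were chosen so the
whole suite exercises every code path at desk scale.

## Known limitations

* 2D, fixed radii, no adhesion, no pressure-based motility hindrance: a
  packed tissue does not slow T-cell transit.
* No diffusible substrates, no chemotaxis, no immune exhaustion or
  recruitment; the immune census is constant.
* The attack rate is a calibrated stand-in, not a measured kinetic
  constant; conclusions should rest on the *contrast between
  initializations*, which is insensitive to its exact value, not on
  absolute kill counts.
* The PCF estimator's edge bias (documented above) makes large-`r` bins
  quantitative only for interior centers.
* h5ad ingestion reads per-cell annotations and a coordinate matrix only;
  expression matrices are never parsed.
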