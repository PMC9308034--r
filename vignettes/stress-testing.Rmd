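---
title: "Stress-testing outpatient care networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-testing outpatient care networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carestress` quantifies how resilient regional outpatient care is to the loss
of physicians. Patients do not pick providers at random: administrative
contact records reveal patient-sharing networks in which two physicians are
linked by the number of patients they both treat. When a physician becomes
unavailable — retirement, quarantine, illness — their patients spill over
preferentially along these links, and whether the system absorbs the shock
depends on the free capacity in exactly that neighbourhood, not on regional
physician density alone. This vignette describes the model the package
implements, the parameters that matter, the synthetic-data generator used
throughout the tests, and the numerical and design choices made.

## The patient-sharing network

Nodes are unique (physician, specialty, municipality) combinations: a
physician practising in two municipalities is two nodes, and removing one
leaves the other active — a simplification that in the data this design is
modelled on affects only a few percent of physicians. The edge weight
$a_{ij}$ counts the **distinct patients** with at least one visit to $i$ and
one visit to $j$ within a ±3-month window; the adjacency matrix is symmetric
with zero diagonal.

Three reading choices deserve note:

* *"3 months" is implemented as 91 days, inclusive at both ends.*
  Calendar-month arithmetic is ill-defined across month lengths; a fixed
  91-day half-width makes the window symmetric and reproducible.
* *A patient counts once per pair.* Even if the same patient co-visits a
  pair of physicians in several separate windows, the weight is a patient
  count, not a visit-pair count. Under this rule it is also irrelevant which
  of the patient's visits "anchors" the window: all anchors are evaluated
  and the pair is counted once.
* Every visit of a patient can anchor a window, so the construction is
  order-free; `build_sharing_network()` agrees with a brute-force
  enumeration of all visit pairs (see `tests/testthat/helper-oracle.R`).

Edges are then thresholded: pairs sharing fewer than `p` patients (default
2) or farther apart than `d` kilometres (default 100, great-circle distance
between municipality coordinates, boundary inclusive) are removed. Each
specialty forms its own layer; cross-specialty edges are discarded.
Physicians outside the giant component of a layer stay in the node set: they
can still receive patients, but only through random relocation (`alpha > 0`
below).

## Capacity estimation

A physician's load is their quarterly patient volume $N$: distinct patients
per calendar quarter, averaged over the quarters in which they are active,
rounded to the nearest integer. The maximum capacity $C$ is estimated from
weekly opening hours: within each (specialty, 5-hour opening-hours bin,
half-open intervals $[0,5), [5,10), \dots$), the top $c\%$ of physicians by
$N$ (set size $\lceil c/100 \cdot n_{\text{bin}} \rceil$, at least one — the
source procedure is silent on small bins) define the bin capacity as the
median of their $N$, which is assigned to every physician in the bin.

Two further rules keep the bookkeeping consistent:

* $C := \max(C, N)$ for every physician. Without this floor, high-volume
  physicians (including the top ones defining the bin capacity) would start
  *over* capacity with negative free capacity, which the displacement model
  cannot represent. Whether the original procedure tolerates overfull
  initial states is not specified; flooring is the conservative choice and
  guarantees $C - N \ge 0$ at initialisation.
* Physicians absent from the opening-hours source receive the median
  assigned capacity of their specialty.

## The displacement model

Each physician starts with $N$ synthetic patient agents; a patient's home
municipality is that of their initial physician. Removing a physician sets
its patients to a searching state. In every displacement round, all
searching patients act once, in uniformly random order:

1. A candidate is drawn. With probability `alpha` the draw is uniform over
   *all* available physicians; otherwise it is proportional to the
   shared-patient weights from the patient's **most recent** physician,
   restricted to available network neighbours. Weights from the most recent
   (rather than the original) physician support chained displacement: a
   patient bumped twice searches from where they last were.
2. The travel-distance rule is applied: if the candidate's municipality is
   farther than `d` from the patient's **home** municipality (always the
   starting one, never the current one), the candidate is redrawn, up to 10
   times; after 10 draws the last candidate is kept regardless of distance,
   so a patient surrounded only by distant physicians is not stuck forever.
3. If the candidate has free capacity the patient is placed: the rejection
   counter resets to zero, the target's free capacity drops by one. If not
   — or if no candidate exists at all (no available neighbours and
   `alpha = 0`) — the rejection counter increments. A patient reaching `s`
   rejections is **lost** and leaves the simulation permanently.

The rejection counter resets on successful placement: `s` bounds one search
episode, not a lifetime budget of moves. A searching patient whose
neighbourhood has been entirely removed (with `alpha = 0`) collects one
rejection per round until lost; this keeps the timing of losses uniform
instead of declaring such patients lost immediately.

Baseline parameters: `s = 10`, `c = 10`, `d = 100` km, `p = 2`,
`alpha = 0`.

### Scenarios

* **Iterative removal** (`run_iterative_removal()`): one uniformly random
  available physician of the specialty is removed per timestep,
  country-wide; displacement runs to quiescence (every patient placed or
  lost) before the next removal; by default the loop stops when one
  physician remains (`until_empty = TRUE` continues to complete removal,
  after which 100% of patients are lost). Per removal step the per-state
  remaining free capacity, located patients and cumulative lost patients
  are recorded. Ensemble default: 100 replicates.
* **Single large shock** (`run_shock()`): `floor(fraction * n)` physicians
  are removed at once, then exactly `s` displacement rounds run, recording
  after each round the number of patients with an active physician;
  whoever is still searching after round `s` is lost. Ensemble default: 10
  replicates.

Replicate `r` of an ensemble uses seed `seed + r - 1`, making every
trajectory exactly reproducible.

## Resilience indicators

From the iterative-removal ensemble, `resilience_curves()` normalises each
state's free capacity and lost-patient count by their initial values and
averages over replicates. `critical_limits()` reports, per state:

* $L_{FC}$ — the fraction of physicians removed when the mean remaining
  free capacity first drops **below 20%** of its initial value;
* $L_{LP}$ — the fraction removed when the mean cumulative lost-patient
  share first exceeds 1%.

Crossings are interpolated linearly between recorded removal steps on the
ensemble-mean curve (not per-replicate); a limit never crossed is reported
as 1 with a censoring flag. The free-capacity limit is defined on the
*remaining* capacity; an alternative reading ("20% of the initial free
capacity has been filled up", i.e. an 80% remaining threshold) exists, but
the remaining-20% definition is the one used consistently with the
threshold guide lines drawn by `autoplot()`.

Per-physician scores:

* **Risk** $R_i = \langle \min((N_j + N_i w_j)/C_j,\, 1)\rangle_j$, the mean
  clamped load physician $i$'s neighbours would carry if $i$ disappeared.
  The weights $w_j = a_{ij} / \sum_k a_{ik}$ are normalised over $i$'s
  neighbourhood so that exactly $N_i$ patients are distributed — the
  reading under which the formula's second term is an expected patient
  inflow. $R_i \in [0, 1]$. Isolated physicians get `NA` rather than 0:
  a physician with no neighbours imposes no measurable neighbour load, and
  0 would conflate "no neighbours" with "no impact".
* **Benefit** $B_i$: initial free capacity $C_i - N_i$, min–max normalised
  within the specialty, so both 0 and 1 are attained. Min–max is the
  simplest map onto $[0,1]$ with both endpoints meaningful; a specialty
  whose physicians all share the same free capacity is flagged degenerate
  (all scores 0).

`regional_levels()` reports the percentage of a state's physicians whose
score strictly exceeds the specialty's nationwide mean.
`score_resilience_regression()` fits, per specialty, the OLS model
$L \sim r \cdot \text{risk} + b \cdot \text{benefit} + \text{const}$ across
states, where the covariates are plain (unweighted) state means of the
physician scores, and summarises coefficients across specialties by mean
and SD. Rank-deficient designs and specialties with fewer than four
complete states are flagged instead of fitted.

## The synthetic-data generator

Real claims data of this kind are access-restricted, so `generate_dataset()`
produces the three input tables with the statistical structure the pipeline
relies on:

* **Municipalities** carry 5-digit IDs whose first digit encodes the
  federal state (up to 9). States are contiguous spatial clusters on a
  compact coordinate box (~300 × 220 km). Each municipality has a Zipf-like
  size weight, creating urban/rural heterogeneity.
* **Physicians** are placed by municipality size weight; weekly opening
  hours are uniform on 15–45 h; a log-normal attractiveness multiplier
  (sdlog 0.75) makes per-physician loads heavy-tailed.
* **Contacts**: patients live in size-weighted municipalities, hold a
  personal repertoire of 2 specialties, and make a Poisson(13) number of
  visits at dates i.i.d. uniform over one year (no seasonality — the
  simplest model compatible with the ±3-month window logic). Within a
  specialty, physician choice is proportional to
  `attractiveness * exp(-distance/locality_scale_km)` with a 30 km scale.

Two optional fields shape the regional structure: `area_scale` grows the
national box (beyond ~2 the travel threshold `d` starts to decouple
neighbouring states, so each region's resilience is governed by its own
capacity rather than country-wide spillover), and
`patient_state_weights` gives states patient populations that differ from
their physician supply — the structural under- or over-supply that makes
some regions genuinely less resilient than others, as regional
physician-density indicators capture.

The defaults were chosen once so that a desk-scale data set (45
municipalities, 15 physicians × 13 specialties, 2000 patients) reproduces
the features that matter downstream: spatially assortative visiting,
heavy-tailed loads, and thresholded specialty layers whose giant component
holds well over half of the physicians. Annual visit frequency (13/patient)
matches the order of magnitude of per-capita physician contacts in European
systems; the compact geography keeps physician density per km² realistic at
small physician counts, so the 100 km travel threshold does not shatter the
layers. What the generator does **not** emulate: true co-visit correlation
structure from referrals, seasonality, age/morbidity strata, opening-hour
correlation with volume, or the empirical magnitudes of any published
per-specialty table. Passing tests therefore demonstrate correctness of the
machinery and robustness of qualitative behaviour, not quantitative claims
about any real healthcare system.

## Numerical choices and degenerate inputs

* Distances are haversine great-circle distances between municipality
  coordinates; the `d` threshold is boundary-inclusive.
* Quarter boundaries are calendar quarters; quarterly volumes are rounded
  to integers (patient agents are discrete).
* Critical-limit crossings interpolate linearly; if the curve sits exactly
  on the threshold at the previous step, the first recorded fraction past
  it is returned rather than dividing zero by zero.
* Empty networks, empty ensembles, unknown specialties and municipalities
  without coordinates raise immediate, named errors; double removal of a
  physician errs rather than silently idempotting.
* All counts are conserved: located + searching + lost = total at every
  step, and no available physician ever exceeds its capacity. These
  invariants are enforced by property tests.

## Problem sizes used in tests

The test suite and the acceptance script run at desk scale, chosen to
exercise every mechanism with comfortable margins: toy networks of 2–10
physicians for exact hand-computed expectations; an exhaustive
probability-tree enumeration (≤4 physicians, ≤12 patients) cross-checking
the Monte-Carlo engine; complete-removal sweeps at ~200 physicians; and a
ranking-stability study on a single-specialty system of 100 physicians in 6
states under capacity percentiles c ∈ {10, 20, 30} and relocation noise
α ∈ {0, 0.15}. Regional resilience *rankings* deserve a note: rankings are
only meaningful where regions genuinely differ. States drawn from one
statistically exchangeable recipe have near-tied true resilience, and the
order of near-ties flips under any parameter perturbation — at any ensemble
size. The stability study therefore uses states that share one physician
supply but carry a gradient of patient loads
(`patient_state_weights = c(3, 2, 1.4, 1, 0.7, 0.45)`) on a map large
enough (`area_scale = 2.5`) that the travel threshold decouples them: six
regions whose resilience differs structurally, which is the situation the
ranking-stability property describes. The design was validated across
several generator seeds before being fixed.

## Known limitations

* Single-specialty layers: no cross-specialty substitution (a lost
  dermatology patient does not fall back to a GP).
* No physician re-entry, part-time capacity, or behavioural response to
  rising load; capacity is a hard ceiling.
* Patient heterogeneity is spatial only; no socio-economic or morbidity
  structure.
* The capacity estimator inherits any bias of the opening-hours source;
  alternative estimators are out of scope.
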