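---
title: "An off-lattice model of cell segregation by contact repulsion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An off-lattice model of cell segregation by contact repulsion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repelsim)
```

## The biological question

When two cell populations expressing complementary Eph receptors and
ephrins meet — for example HEK293 cells stably expressing EphB2 next to
cells expressing ephrinB1 — they segregate into discrete territories and
form sharp tissue-like borders. Three classes of mechanism could drive
this: differential adhesion, differential cortical tension, and contact
repulsion (contact inhibition of locomotion, CIL), in which a heterotypic
collision triggers collapse of cell processes and migration away from the
contact. `repelsim` implements an agent-based model in which the measured
contact behaviour of such cells — how long contacts last, and how often
they end in a collapse response — is fed directly into a stochastic
simulation, so that the sufficiency of repulsion versus adhesion can be
tested in silico.

## The cell model

Each cell is a deformable ring of eight membrane nodes around a centroid.
Geometry is set by the cell radius (7.5 µm; 15 µm diameter) and an ideal
bond length between adjacent nodes (the octagon edge, `2 r sin(π/8) ≈
5.74` µm). One node is the **leader**: it defines the migration direction,
and the cell translates toward it at a fixed speed (0.75 µm/min). In free
migration the leader is re-chosen uniformly at random with probability
0.2 once per one-minute decision tick, giving a persistent random walk.
Cells live in a circular arena (500 µm diameter at full scale) with a hard
wall, and cannot overlap: membrane nodes of different cells are kept at
least 1 µm apart by the constraint solver.

Internally the migration direction is carried as a continuous heading
angle; every event that reassigns the leader (repulsion, spontaneous
change) also sets the heading to that node's direction, and cohesive
pulling rotates the heading continuously. This avoids quantising collective
direction changes to the eight node positions.

### Adhesion

When membrane nodes of two different cells approach within the contact
distance (3 µm), they form an **adhesion link**; a node holds at most one
link. A link is a compliant tether: the linked node pair can separate up
to `linkStretch` (4 µm) — membranes slide along each other while the cells
remain in contact — before the constraint solver pulls it back. Links
break stochastically. The mean measured contact duration `T` of a pair
class sets the per-minute breaking rate `η = 1/T`, giving the per-minute
break probability `p(break) = 1 − exp(−η)`; breaking is evaluated once per
decision tick (one simulated minute), on the same per-minute probability
scale on which the behaviour measurements are tabulated. Because a link is
one shared object while durations were measured per cell type, the hazard
of a heterotypic link is the mean of the two focal-cell hazards; for the
measured values (24 vs 26 min) the resulting mean lifetime is within 5% of
both inputs. After a break, the two cells involved do not re-link *to each
other* for a refractory minute; all other partners are unaffected.

### Repulsion

When a link breaks, each endpoint cell independently evaluates a collapse
response with its own probability `p(repulsion)` (the measured per-contact
collapse frequency). On success the cell repolarises **away from the
source of the activating signal**: its new heading is opposite the
resultant of the broken contact and all remaining contacts with cells of
the collapsing partner's population. With a single contact this reduces
exactly to the membrane point opposite the broken node — the elementary
rule — while a cell surrounded on one side is consistently pushed toward
its free edge, as in CIL repolarisation. The collapse retracts the cell's
processes: all its remaining links are released (without triggering
further collapse signalling in the partners), and the cell keeps the
escape heading for a committed period `escapeMin` during which spontaneous
direction changes are suppressed and the released partners are avoided.
The committed period is a pair-class parameter encoding the measured
post-repulsion migration behaviour: 6 min where tracked cells showed a
several-minute displacement burst (heterotypic repulsion of EphB2 and
ephrinB1 cells; homotypic repulsion of EphB2 cells after N-cadherin
knockdown), 3 min where they did not (homotypic repulsion in controls,
all responses of kinase-inactive EphB2 cells). The escaping cell remains
adhesive toward every *other* cell on its way, so escapes in a confluent
tissue are caught and do not turn into long ballistic flights.

In the **adhesion-only** mode (`directed = FALSE`) the collapse machinery
is off: when a link breaks the focal cell re-chooses its leader uniformly
at random ("random migration after contact"), nothing detaches, and there
is no committed escape. Contact durations are then the only thing that
distinguishes homotypic from heterotypic encounters.

### Cohesion

A repelled cell pulls on the neighbours it is linked to: each such
neighbour rotates its heading toward the repelled cell's new direction by
the fraction `pullWeight` (0.5 by default; the magnitude is a free
parameter of the model). The pull acts once per neighbour per repulsion
event and only on direct link neighbours; influence propagates further
only over subsequent steps.

### The update step

One step corresponds to 0.5 s, so 50 000 steps are ≈ 7 h of simulated
time. Each step applies, in order: link formation; (on decision ticks)
link breaking with repulsion, then spontaneous direction changes;
displacement; cohesive pulling; constraint enforcement. Constraint
enforcement is iterative position projection — bond lengths toward the
ideal bond, nodes toward the ideal radius (hard-capped at twice it,
keeping the membrane bounded), stretched links back to `linkStretch`,
inter-cell node separation at least `minSeparation`, nodes inside the
arena — for at most 10 sweeps, exiting early when the largest correction
falls below 10⁻⁴ µm. All randomness is drawn from R's generator, so a
seed makes runs bit-reproducible.

## From measured behaviour to parameters

`behaviourMeasurements()` ships the mean contact durations and collapse
frequencies for every measured condition (control and N-cadherin
knockdown, homotypic and heterotypic, EphB2/kiEphB2/ephrinB1).
`pBreakFromDuration()` converts durations to per-minute break
probabilities; `repulsionFrequencyPerMin()` and `repulsionRatio()`
compute the summary statistic of differential repulsion (collapse
frequency per contact divided by duration; heterotypic over homotypic).
`buildPreset()` assembles the ten shipped conditions: the measured
control and kinase-inactive co-cultures, the two adhesion-only controls
(measured durations, and a 500:1 homotypic:heterotypic duration ratio),
the N-cadherin knockdown, and the five single-parameter manipulations of
knockdown or control values used to dissect the roles of the repulsion
ratio and of homotypic contact duration. Three tabulated `p(break)`
values differ from the formula value in the third decimal (printed 0.018,
0.046 and 0.063 versus computed 0.0174, 0.0465 and 0.0645); the formula
values are used and the discrepancy is recorded in the preset notes — the
printed table appears to round intermediates.

For the `ncad_kd_hom45` manipulation the source states only the
EphB2-side change (homotypic duration 24 → 45 min). The ephrinB1
homotypic duration is scaled by the same factor (21 → 39.4 min), which
makes the ephrinB1 repulsion ratio match its value under the
heterotypic-shortening manipulation exactly as the EphB2 ratios match
(both 3.4); this keeps the two "same ratio, different route"
conditions symmetric for both populations.

## The in-silico assays

`initSegregation()` packs both populations intermingled (jittered
hexagonal packing at the study density — 800 cells of 15 µm diameter in a
500 µm arena, packing fraction ≈ 0.72 — relaxed by the constraint solver;
labels assigned uniformly at random in exactly equal numbers).
`initBoundary()` mimics the moment two confluent fronts meet after
barrier removal: the dividing line is a fixed smooth curve (two sinusoidal
modes, amplitudes 0.6 and 0.25 of the mixing band) with a thin
interdigitation strip in which cells exchange labels pairwise. The
interface *shape* is part of the assay design and identical across
replicates, like the physical barrier of the wet assay; packing jitter,
interdigitation and the dynamics carry the replicate-to-replicate
stochasticity. A mixing band of zero gives a perfectly straight border.
The band realises a ragged meeting line rather than a band of label
swaps: deep transplanted cells would be an initial condition the physical
assay cannot produce, and migrating cells cannot clear them on the assay
timescale.

`runExperiment()` runs replicates with independent seeds and records the
assay metric over time: the **normalised border length** for boundary
assays and the **segregation index** (mean fraction of six nearest
neighbours sharing a cell's label) for segregation assays.
`compareConditions()` applies a two-sided exact Mann–Whitney U test to
the per-replicate final metric values; with complete separation of ten
versus ten replicates the exact p-value is 2/C(20,10) ≈ 1.1 × 10⁻⁵,
consistent with the p ≈ 2 × 10⁻⁵ scale reported for such comparisons.

## Quantitation

* `borderLength()` finds, for every cell, its nearest heterotypic
  neighbour; the segments between **mutual** nearest heterotypic
  neighbours trace the interface ("short segments between neighbouring
  cells"), their midpoints are chained greedily starting from the most
  peripheral one, and the polyline length is the border length. One-sided
  pairs — a cell deep in its own territory whose nearest heterotypic cell
  sits far away at the border — do not represent the interface and are
  dropped; with them the metric saturates at several times the interface
  width even for a perfectly straight border. On a straight split of grid
  points the metric recovers the interface width to within a few percent
  (the chain spans the outermost midpoints, so a fixture with fine
  spacing is used for the oracle). The instantaneous reading fluctuates
  from frame to frame, so per-replicate endpoint values average a short
  window of recorded frames (`finalValues(window = 5)`).
* `clusterParticleAnalysis()` mirrors ImageJ-style particle analysis:
  rasterise one population to a binary mask (1 µm/pixel; cells as filled
  node octagons, or discs of the mean single-cell area for plain point
  sets), label connected components with 8-connectivity, discard blobs
  below 500 µm², and convert areas to cell counts at 200 µm² per cell.
* `extractContactEvents()` segments cell tracks into contact episodes
  (centroid distance ≤ 17 µm — cell diameter plus contact range — over
  consecutive frames), yielding cell-centric events with duration, the
  pair axis at contact start, the post-contact direction over three
  frames, the angle θ between them, a collapse flag (from an annotation
  column or a simulation event log) and a censoring flag for further
  collisions within 20 min. `migratesAway()` applies the literal
  π/2–3π/4 classification band; the upper bound is configurable to π
  because the literal band excludes straight-back movement, which may or
  may not be intended in the original rule — the literal rule is the
  default. `displacementAfterRepulsion()` profiles post-collapse
  displacement in 3-min bins over a 20-min window for uncensored collapse
  events.

## Numerical and design choices

* **Hazard evaluation interval.** The tabulated `p(break)` values are
  per-minute probabilities; the model evaluates them once per one-minute
  decision tick rather than rescaled to the 0.5-s integration step.
  Evaluated per step, extreme conditions (the 500:1 duration ratio)
  would redirect undirected cells every couple of seconds and freeze
  them; per-tick evaluation keeps the measured mean durations (the
  geometric mean lifetime is `1/p(break)`, within 2% of the measured
  duration) while leaving a one-minute floor on direction persistence.
* **Collapse as detachment.** Movies of these cells show that a
  collapse response retracts processes and the cell disengages; in the
  model the repelled cell releases all its links. Without release, a
  cell tethered by five neighbours can never leave a contact, and the
  measured contact durations would no longer control anything
  observable.
* **Compliant tethers.** `linkStretch` of 4 µm (twice the contact
  distance) lets contacts slide without detaching. Harder tethers freeze
  the tissue; unbounded ones make "contact" meaningless.
* **Constraint solver.** Position projection with at most 10 sweeps per
  step; the overlap/exclusion distance (1 µm) is deliberately smaller
  than the contact (sensing) distance (3 µm) so membranes can slide past
  each other — with exclusion at the sensing range the packing at the
  study density jams.
* **Ties and determinism.** Link formation is greedy in node order with
  nearest-partner choice (ties: lower cell id, then node index); one
  seeded generator drives everything; equal seed and configuration give
  byte-identical outputs.

## What the generator emulates, and what it does not

The synthetic assays reproduce the study conditions: cell numbers, arena,
density, speeds and the measured behaviour values. They do not model cell
division or death, three-dimensional piling-up and compaction of clusters
(explicitly absent from a 2D model), receptor signalling kinetics or
desensitisation (context-dependent homotypic behaviour is handled by
choosing the matching preset), or the image-segmentation noise of real
micrographs. Passing tests on simulated data therefore show that the
*model pipeline* behaves as specified, not that real cells do; the
quantitation functions, however, accept external track tables of the
standard form (frame, time_min, cell_id, population, x_um, y_um) and can
be applied to measurements.

## Scale of the shipped test battery

The package's own test battery runs the boundary-assay conditions at a
quarter of the full cell count (200 cells in a 250 µm arena, preserving
density) for 10 000 steps with 10 replicates per condition, which keeps
the whole suite fast on a laptop; the full-scale setup (800 cells,
50 000 steps) is the default of `experimentConfig()`. At the reduced
scale only about 1.4 h of tissue time is simulated, so sharpening is
partial: condition orderings are assessed statistically rather than by
matching full-scale magnitudes, and some of the weaker single-condition
effects sit near the significance threshold at this scale.

## Known limitations

* Contact durations are encoded as single-link lifetimes, and the link
  calibration is exact (the Monte-Carlo lifetime tests). Distance-based
  contact *episodes* extracted from sampled tracks deviate from the
  calibrated values in both directions: brief separations shorter than
  the 3-min frame interval merge episodes, while a collapse toward a
  third partner detaches the cell and truncates its other contacts.
  Collapse attribution on sampled tracks is similarly lossy — a repelled
  cell separates at ~1.5 µm/min, so the distance-defined episode end can
  lag the collapse by more than one frame and the response goes
  unattributed. Contact-behaviour calibration is therefore asserted at
  the event level (the simulation event log), not through the
  track-episode route.
* The repulsion ratio enters through per-link hazards, so per-cell event
  rates also scale with the number of simultaneous contacts; the summary
  statistic is preserved, absolute event rates in confluent tissue exceed
  the sparse-culture measurements.
* The border-length metric is a greedy chain over mutual-nearest
  midpoints; it is rotation- and translation-invariant and tracks
  raggedness monotonically, but its absolute value depends on cell
  spacing near the interface.
* The post-repulsion displacement *burst* is modelled as a longer
  committed escape at constant speed, not as a transient speed increase.
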