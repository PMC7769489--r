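---
title: "Enriched Semantic Event Chains: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enriched Semantic Event Chains: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esec)
```

## The representation

A tabletop manipulation is described not by trajectories but by the *changes
of qualitative spatial relations* between a small set of abstract roles: the
hand, the ground, and up to three manipulated objects numbered by the order
in which their touching state first changes. Distractor objects whose
touching relations never change receive no role and are invisible to the
representation.

For every unordered pair of the five roles (there are `choose(5, 2) = 10`)
three relation types are tracked:

* **TNR** — touching (`T`) vs non-touching (`N`), decided by cube collision;
* **SSR** — static spatial relations: above/below (`Ab`/`Be`), their touching
  counterparts top/bottom (`To`/`Bo`), around (`Ar`, `ArT`), containment
  (`In`/`Sa`), and `O` for pairs too far apart to relate;
* **DSR** — dynamic relations over a short time window: moving together
  (`MT`), halting together (`HT`), one object moving across a static one
  (`FMT`), getting closer (`GC`), moving apart (`MA`), stable distance
  (`S`), and `Q` when none applies or the pair is too far.

Three bookkeeping symbols complete the alphabets: `U` for pairs involving a
not-yet-assigned role, `A` for absent (occluded) objects, `X` for destroyed
objects.

The *enriched Semantic Event Chain* (eSEC) is the 30-row matrix whose
columns are the successive distinct values of this relation vector: a new
column is emitted whenever any of the 30 entries changes and the changed
state persists. Because columns are events rather than time steps, the
representation is invariant to the tempo of the action.

```{r example}
tr <- generate_scenario("put_on_top", seed = 1)
e <- build_esec(tr)
e$mat[c("H,1:TNR", "1,2:TNR", "1,G:TNR", "H,1:DSR", "1,G:DSR"), ]
```

## Geometry and parameters

All objects are axis-aligned boxes (y is up; units are metres and seconds).
The relation extractor is controlled by `relation_params()`:

| parameter       | default | meaning                                           |
|-----------------|---------|---------------------------------------------------|
| `eps_touch`     | 1 mm    | face-contact tolerance for touching               |
| `xi_stable`     | 1 cm    | distance-change bound for "Stable"                |
| `xi_motion`     | 0.1 m   | distance-change threshold for GC / MA             |
| `theta`         | 10 fr   | dynamic window (0.5 s at 20 fps)                  |
| `eps_move`      | 5 mm    | centre displacement that counts as "moving"       |
| `far_threshold` | 1 m     | centre distance beyond which a pair has no relation |
| `debounce`      | 12 fr   | persistence required before a change becomes an event |

Notes on the less obvious choices:

* The stability, motion and farness cut-offs play three different roles even
  though a single symbol is conventionally used for all of them; they are
  three parameters here. The 1 m farness default is our choice — nothing in
  the relation definitions pins it down — and it is configurable.
* Exact face coincidence has measure zero in floating point, so touching is
  a proximity band (`eps_touch`) plus interpenetration, covering all six
  face configurations of two boxes.
* `eps_move` replaces a strict inequality between two float positions,
  which would be meaningless under numerical noise.
* Containment (`In`) requires the contained box to reach at least 1 mm
  below the container's rim. Without that margin, a cube merely resting on
  another with an aligned footprint satisfies the containment comparisons
  through boundary equalities, and the label flickers with float dust.

### The dynamic window

The dynamic relation at frame *f* is judged over the forward window
[*f*, *f* + θ]: a far pair is `Q`; a pair touching *at frame f* is
MT/HT/FMT according to which of the two centres move more than `eps_move`
across the window; otherwise a distance change beyond `xi_motion` gives
GC/MA, below `xi_stable` gives `S`, and anything between gives `Q`.

Keying the touching branch on the current frame (rather than requiring the
same touching state at both window ends) is deliberate: the both-ends form
leaves θ-frame bands around every touch and untouch event in which no
clause applies, which would inject a spurious `Q` event into every pick and
place. On steady-state windows the two forms agree exactly.

### Event compression and debounce

Threshold crossings produce transients: when a motion starts or stops, the
windowed distance change sweeps through the `Q` band between `xi_stable`
and `xi_motion`, and window positions straddling a phase boundary
anticipate the next phase by up to θ frames. All such transients last at
most about θ frames, which is why the event debounce (12 frames) must
exceed θ (10): anything shorter is threshold flicker, anything meant as an
event persists much longer. Two further details:

* micro-flicker healing: within each row, runs of ≤ 2 frames are absorbed
  into the preceding state before compression. A sawing motion, for
  instance, reverses direction every stroke; at each reversal the net
  window displacement of the tool passes through zero for a frame, and
  without healing these one-frame `HT` blips would fragment the sustained
  `FMT` state into sub-debounce pieces.
* the chain ends one debounce interval after the hand's pairs have all
  returned to non-touching at far distance (or at the trajectory end).

The first two columns emerge from the staging convention rather than from
manipulation: column 1 is the initial scene with the hand far away (all
numbered roles unborn, `H,G = N/O/Q`), column 2 is the hand entering the
workspace (`H,G` becomes `Ab`/`GC`). They are identical across all ten
actions, as a recognition-neutral prefix should be. We do not pre-assign
`H,1` in column 2: numbered roles are `U` strictly before their first
touching change, and the approach itself is what the second column encodes.

### Static disambiguation

Several directional tests can hold at once (the printed left/right tests
are one-sided, so overlapping arrangements admit multiple candidates). The
*shadow* rule resolves this: each candidate's facing surface is projected
onto the partner's opposing surface and the label with the largest
projected intersection area wins; ties break by the fixed priority
Ab > Be > L > R > F > Ba. The view-dependent side labels L/R/F/Ba collapse
to `Ar`. Containment is more specific than any directional label and takes
precedence. Touching upgrades Ab→To, Be→Bo, Ar→ArT.

## The simulator

`generate_scenario()` produces the study's ten scripted actions (chop, cut,
hide, uncover, put on top, take down, lay, push, shake, stir) as keyframed
cube scenes: approach, grasp, lift/transport/oscillate, action-specific
phase, release, withdraw. Scenario durations are drawn per action from a
truncated normal whose location is calibrated so the truncated mean equals
the published per-action mean, and whose spread and range are the published
SD and range. Sizes, placements, entry direction and distractor cubes are
randomised per scenario.

Design choices that matter downstream:

* **Fixed speeds, stretchable holds.** Motion speeds inside a script are
  constants; the drawn duration is absorbed entirely by hold phases. Event
  sequences therefore do not depend on the drawn duration — the
  event-timing invariance the representation promises.
* **Ring workspace.** Manipulated objects sit on a ring around the ground
  centre and transports follow the ring. Along an arc the distance to the
  ground centre is constant, so carrying reads as `S` rather than as an
  arbitrary GC/Q/MA sequence that would depend on where the transport
  passes relative to the workspace centre.
* **Phases sized against the debounce.** Every intended relational state
  persists for roughly 17 frames or more, and every known transient (dead
  bands, anticipation, fast final descents) stays well below 12 frames.
  This is what makes all scenarios of a class compress to one canonical
  column sequence; the margins were chosen once from the threshold
  geometry, and the test suite checks class-level consistency across seeds.
* **Cut vs chop.** Both divide the target (its `destroyed` flag is set at
  the division, turning its rows to `X`): cut saws — a sustained
  one-object-moving-on-another (`FMT`) episode — while chop strikes
  repeatedly, alternating contact and retreat. Hide sinks a cover over the
  target and sets its `absent` flag when fully covered; uncover starts with
  the target geometrically enclosed by the cover and reveals it when the
  cover lifts (no flag needed, and the absent flag is monotone by
  invariant). Stir inserts a short tool into a container, producing the
  containment relation `In`.
* **Lay** reshapes a tall slab into a lying one by box morphing (corner
  interpolation) — the axis-aligned world has no rotations, but the
  relational signature (hand riding the object down while the object slides
  on the ground, `MT`/`FMT`) is the point.

What the generator does *not* emulate: human kinematics (velocity
profiles are piecewise constant), sensor noise and occlusion (geometry is
exact; absence/destruction are annotations, as in the source data),
non-rigid objects, and within-hand shape cues. Consequences: real
recordings would show threshold flicker from tracking noise that our
debounce may or may not absorb, and intra-class variability here is
strictly relational-timing variability. Passing tests show the
representation and classifiers behave as designed under the study's
conditions, not that they are robust to arbitrary real-world capture noise.

## Progressive classification

The similarity of two eSECs right-pads the shorter matrix by repeating its
last column, compares TNR/SSR/DSR per pair-cell (each differing category
contributes 1/3), and averages over the 10 × k cells; similarity is
`(1 − D) · 100` percent.

The decision rule watches the mean prefix similarity per class as columns
arrive and commits at the earliest column where a single class is the
strict argmax, leads the runner-up by at least `margin` and *remains* the
strict argmax through the final column. The description of the original
rule ("similarity for one class remained high while all others were low")
is not a formula; persistence-to-the-end operationalises "remained", the
margin operationalises "high vs low", and `margin = 0` reproduces
earliest-disambiguation behaviour. Predictive power is the percentage of
columns spared after the prediction column. Train/test splits are
stratified by action and seeded; the split fraction is a parameter.

## Information and observer models

For each sub-table (T, S, D) the symbols of one column are concatenated
into a *column code*; the likelihood of an action's code at a column is the
fraction of the ten actions sharing that code there, with actions whose
chains have already ended contributing an `ENDED` pseudo-code. A shared
code has likelihood 1; a code unique among ten has 0.1. Self-information is
−log₂ p bits, and cumulative information is its running sum. Bits of the
sum models (T+S, T+D, S+D, T+S+D) add across sub-tables; "Overall" treats
the whole 30-symbol column as one code and is computed independently.
Canonical tables (one eSEC per action: the modal column sequence over that
action's scenarios) are the reference set.

Observer response models regress the presence of a button press in each
action step on the step's absolute information, the accumulated
information, and their interaction, via maximum-likelihood logistic
regression with stepwise-forward entry (likelihood-ratio test, enter at
p < 0.05 — the conventional default, configurable). Each trial contributes
one row per step up to and including its response column; later steps are
unobserved because the display blanks at the response. Fits are compared by
BIC (AIC is also reported), with McFadden's pseudo-R² against the
intercept-only null.

The synthetic observer (`generate_responses()`) draws Bernoulli responses
per step from a chosen generating model. The parameter-recovery check uses
a pure-cumulative observer on the dynamic sub-table (intercept −3.5,
cumulative slope 0.45 per bit, 20 trials per action) and fits pooled across
actions: with ten actions the per-model information profiles are highly
correlated (the sums share components), and pooling gives the comparison
enough events to separate them; the generating model then wins the BIC
ranking in well over 80% of seeded replicates.

## Problem sizes

The acceptance script derives the canonical cut chain from 30 scripted cut
scenarios — the study's scenario count per action — and the likelihood
worked examples from constructed ten-action code sets. The test suite
evaluates classification on a 30-per-action dataset (300 scenarios,
half/half split), checks class-consistency on 5–15 seeds per action, runs
the relation oracle on several hundred random cube pairs, and the
model-recovery property on 50 seeded replicates.

## Known limitations

* The canonical column sequences are a property of the scripted world;
  their exact counts (and hence per-action predictive power values) would
  differ for other choreographies of the same actions.
* The O/Q farness cut-off and the two start columns are conventions; both
  are documented parameters rather than claims about the underlying
  definitions.
* `classify_progressive()` is quadratic in training-set size per test
  matrix; for the study's scale (hundreds of chains, ≤ 20 columns) this is
  negligible.
* The stepwise-forward logistic fits inherit the usual caveats of stepwise
  selection; coefficients are not interpreted, only model rank by BIC.
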