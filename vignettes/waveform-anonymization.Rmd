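---
title: "Anonymizing clinical waveform data: the model behind waveanon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing clinical waveform data: the model behind waveanon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveanon)
```

## The problem

Physiological recordings — airway flow, airway pressure, oxygen
saturation — are time-continuous and highly individual: whole-curve shape
can re-identify a subject even after explicit identifiers are removed.
Releasing such data therefore needs *k-anonymity* (each released group
contains at least *k* subjects, bounding a linking attack to a 1/k guess)
and *t-closeness* (the distribution of sensitive values inside each group
stays within distance *t* of the population distribution, defeating
distribution attacks).  Point-wise generalization destroys the temporal
dynamics that make waveform data useful, so `waveanon` generalizes *whole
curves*: it groups curves into equivalence classes and releases, per
class, only a lower/upper envelope (the *hull*) on a regular time grid.

## The procedure

For each time segment (see *Splitting* below) the pipeline runs:

1. **Distances.** All pairwise discrete Fréchet distances between the
   aligned curves.  The Fréchet distance is a metric (unlike DTW) and
   respects curve shape rather than pointwise alignment.
2. **Distribution clustering.** A surrogate population distribution:
   scanning curves in id order, a curve joins the first cluster whose
   reference curve lies within the distribution sensitivity `s_d`,
   otherwise it founds a new cluster.  Singleton clusters are merged into
   the nearest cluster.  A cluster of *n* curves contributes *n*
   occurrences of its reference to the distribution.
3. **Bucket Tree.** A fully balanced binary tree of similarity buckets:
   every node of size ≥ 2 splits by farthest-pair seeding, nearest-seed
   assignment, and rebalancing so that each child keeps at least
   `ceil(f * n)` members.  Each level partitions the dataset; the user
   picks a depth `depth_b` instead of an explicit maximum cost.  A
   bucket's *error* is the distance from its reference to its farthest
   member; treating each taken curve as the reference costs at most that.
4. **ECS Tree.** The Equivalence Class Size tree turns the selected
   bucket sizes into per-class, per-bucket quotas by recursive
   target-halving with largest-remainder apportionment, stopping where a
   component reaches 1 or a child would drop below *k*.  The leaves are
   the initial (empty) equivalence classes; quotas preserve the
   population proportions, which is what carries t-closeness.
5. **Distribution phases.** Classes are filled greedily from the buckets
   (the pick minimizing the class hull's information-loss increase),
   serving the proportionally most under-served bucket first.  A pick
   whose post-insertion loss exceeds the drop threshold `d` is dropped
   from the dataset (it stays attached to the class but is excluded from
   all further computation); a loss in `(s_eqc, d]` splits the class into
   its ECS children; a loss above `max_cost` blocks that bucket for the
   class.  Unfinished classes are then dissolved into other unfinished
   classes (unmarked redistribution), then into finished ones with the
   cost constraint (constrained), and finally without it (relaxed, the
   drop threshold still applies), so every curve ends in a released
   class, as a dropped member, or — if no class can be released — in an
   explicit infeasibility error.
6. **Report.** Per class: the hull, the generalization loss GLM (mean
   hull width over the value-domain width; 0 for single-member classes),
   the median relative error MRE (pooled median distance of members to
   the nearer hull bound, at hull resolution), the bucket-error bound
   `t_i = Σ err_j · p_j`, and the exact `t` (EMD between the class's
   cluster histogram and the population, Fréchet ground distance).

### Splitting (the semi-local decision)

Whole-recording grouping is a global decision; splitting the time axis
into segments and re-running the whole pipeline per segment makes it
semi-local: curves may change classes between segments, which lowers
information loss for long or heterogeneous recordings.  Three modes:
fixed-length (with a remainder-merge threshold), manual boundary lists
(gaps allowed, data between segments is withheld), and windowed-Fréchet:
a sliding window scores local similarity by the mean pairwise Fréchet
distance, and the lowest-mean windows become segment starts, so segments
reach from one region of similarity to the next.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `k` | curves | 3 | minimal class size; 3 is the smallest value that hides the members between the released bounds |
| `s_d` | Fréchet distance | (required) | cluster join threshold; too large → one cluster (trivial 0-closeness), too small → many clusters, high t |
| `f` | fraction | 0.4 | Bucket Tree balancing factor; must be ≤ 0.5 to be satisfiable |
| `depth_b` | levels | 1 | bucket selection depth; implies the maximum cost |
| `s_eqc` | GLM | 1.0 | class-split threshold (inactive at 1.0) |
| `d` | GLM | 1.0 | drop threshold (inactive at 1.0) |
| `max_cost` | GLM | `s_eqc` | insertion cost cap during constrained phases |
| `hull_resolution` | s | 0.05 | hull grid step; 50 ms suits 50 Hz signals, use 0.5 s for slow signals |

With the defaults `d = s_eqc = max_cost = 1.0`, neither dropping nor
splitting nor blocking occurs — the configuration used for routine runs.

## Design choices where the design was open

* **Hull = pointwise envelope.**  "Convex hull" is implemented as the
  per-grid-point lower/upper envelope: the release must stay a function
  of time, and the evaluation metrics (GLM, MRE) are defined on upper and
  lower bounds per time step.
* **Fréchet ground distance and axis scales.**  Time (seconds) and values
  (signal units) are incommensurable; the ground distance is Euclidean on
  `(t * time_scale, v * value_scale)` with `time_scale = 0` by default —
  distances are computed on values at coupled indices of the identically
  resampled curves, time entering through the coupling order only.  Both
  scales are exposed rather than hidden.
* **t normalization.**  Ground distances for the EMD (and the bucket-error
  bound) are divided by the maximum pairwise cluster-reference distance,
  so `t` is comparable across datasets and lies in `[0, 1]` for
  transports between references.  Disable with `normalize_t = FALSE`.
* **Scan orders.**  Clustering and greedy fills scan in ascending curve
  id; farthest-pair and remainder ties break toward lower ids/indices;
  donors dissolve smallest-first.  This makes the whole pipeline
  deterministic — identical inputs give byte-identical reports — at the
  price of an arbitrary but documented order.
* **Bucket-quota fill order.**  The proportionally most under-served
  bucket is served next, ties toward the larger quota, so a class is
  seeded from its dominant bucket.
* **Marking rule.**  A class is marked when its quota is met exactly, or
  when the buckets cannot serve it further but it holds at least `k`
  members with per-bucket counts within ±1 of its quota proportions.
* **Dropped members.**  A dropped curve stays attached to the class that
  dropped it (it is enumerated in the report) but contributes to no hull,
  GLM, MRE or t computation, and does not count toward `k`.
* **Stranded curves.**  A class marked through the ±1 rule can leave
  curves in a bucket; after the relaxed phase these are placed into the
  least-loss marked class (dropped there if the loss exceeds `d`), so
  curve conservation holds at every phase boundary.
* **Padding.**  Curves are aligned by holding the first/last value to the
  common frame; otherwise a class whose shortest member ends early would
  be only (k−1)-anonymous for the remaining time.  Padded samples take
  part in distance computations as well as in hulls; they lie inside the
  curve's own value range.
* **Windowed-split convention.**  The segment boundary is the *start* of
  a selected window; selected boundaries must be at least one window
  length apart and strictly inside the frame, earliest offset winning
  ties.

## Numerical choices

The discrete Fréchet distance is the Eiter–Mannila coupling recurrence,
computed in C++ over the union grid of the common frame (curves with
unequal grids are linearly resampled first).  The EMD is an exact
transportation linear program (two-phase simplex) on the normalized
histograms, reduced to the positive-mass supplies and demands, with one
redundant demand constraint dropped.  Hull grids clamp their final point
to the segment end.  Degenerate inputs are defined explicitly: a
single-member class has GLM 0; a width-zero value domain gives GLM 0 with
a warning; two mutually distant curves at `s_d = 0` still form one
cluster (the forced singleton merge).

## What the synthetic generator does and does not show

`generate_breath_curves()` produces seeded sinusoid surrogates
`v(t) = A sin(2π RR/60 t + φ) + ε` with per-curve jitter in amplitude,
phase and rate, optional irregular sampling, and known cluster labels;
`emulate_paper_shapes()` fixes the layout of three ventilation-trial
recordings (12 × 8 s @ 50 Hz flow; 28 × 4 s @ 50 Hz pressure; 12 × 400 s
@ ~0.5 Hz irregular saturation).  The pipeline only reacts to the
*similarity structure* of its input, which the generator controls
exactly — that is what makes parameter-recovery tests possible.  It does
not emulate ventilator dynamics, physiological artifacts, sensor dropouts
or non-stationary rates, so passing tests demonstrate algorithmic
correctness, not clinical realism of any particular release.

## Known limitations

* The bucket-error bound `Σ err_j · p_j` is a heuristic
  over-approximation, not a theorem: integer quota rounding adds a
  distribution mismatch the bound ignores.  With realistically noisy,
  heterogeneous curves the exact t stays below the bound (the test suite
  checks this across seeded runs); for near-duplicate clusters with odd
  class sizes the exact t can exceed it.  The reported exact t is the
  authoritative number.
* Proportional quotas mean every class samples every bucket: classes are
  deliberately *mixed* with respect to the population clusters.  Users
  expecting homogeneous classes are expecting a different (and weaker)
  privacy model.
* Repeated publication of overlapping datasets is out of scope
  (m-invariance is not implemented), as are reconstruction-style releases
  and randomized member selection.
* Cluster references stay the first member added (no medoid updates), and
  dropping is per segment — a curve can be dropped in one segment and
  used in the next.

## Problem sizes used by the test suite

The suite exercises 8–28 curves of 50–400 samples (plus a 400 s / 1 Hz
set for the segmentation checks) and 20 seeded end-to-end runs over
k ∈ {3..6}, depth ∈ {1..3} and all three split modes; oracle comparisons
use 100 seeded Fréchet pairs and 100 seeded histogram pairs.  These sizes
keep a full run in well under a minute while covering every phase of the
algorithm; the pipeline itself handles the 150-curve single-breath scale
in seconds.
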