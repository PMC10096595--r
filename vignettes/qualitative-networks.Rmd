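---
title: "Qualitative networks: model semantics, stability bounds and in silico screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative networks: model semantics, stability bounds and in silico screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualnet)
```

## The model class

A *qualitative network* (QN) generalises a Boolean network. Each node $X$
carries an integer activity level in a finite range $[\min_X, \max_X]$
(a protein's phosphorylation state, a gene's expression, the intensity of a
phenotype such as proliferation). Signed edges say who regulates whom. Each
node has a *target function* $T_X$ over the levels of its regulators; unless
an explicit expression is given it defaults to

$$T_X = \mathrm{avg}(pos) - \mathrm{avg}(neg),$$

the average of the activator levels minus the average of the inhibitor
levels. When a regulator $Y$ with range $[a, b]$ feeds a node with range
$[a', b']$, its level first passes through the linear rescaling
$(y - a)(b' - a')/(b - a) + a'$, so that "fully active" means the same thing
on both sides of the edge.

The dynamics are synchronous and conservative: at every tick each node
compares its target with its current level and moves *one* level toward it
(clamped to its range). Because the state space is finite and the update
deterministic, every trajectory ends in an attractor: a *fixed point* (one
state) or a *loop* (a cycle of states). When different initial states reach
different attractors the network *bifurcates* — the discrete signature of
multistability.

Three conventions complete the default function; each lives in a single
internal function (`default_target_ast()`) so it can be swapped wholesale:

* a node with activators and inhibitors uses `avg(pos) - avg(neg)`;
* a node with only inhibitors treats `avg(pos)` as its own maximum level —
  inhibition is understood as opposing full activation, so an unopposed
  inhibitor can actually silence the node;
* a node with no regulators holds its current level. This makes unregulated
  inputs (ligands, mutation status, transcriptional state) *background
  dials*: they keep whatever a background clamps them to and contribute no
  spurious dynamics of their own.

The second convention is genuinely a choice (tools differ here); it is
deliberately isolated and documented so users who prefer
`0 - avg(neg)` can change one function and re-run.

## Exact arithmetic

Targets are evaluated in exact rational arithmetic (`qn_rational`), never in
floating point. The grammar of explicit expressions — integer constants,
`var()` references, `+`, `-`, constant multiplication, constant division,
n-ary `avg`/`min`/`max`, unary `floor`/`ceil` — is restricted precisely so
that (i) every value is a small rational with a bounded denominator and
(ii) every operator is monotone in each argument. (i) means fixed points are
decided by exact comparison: a target of $v + 1/2$ *moves* the node, which is
why loops with fractional targets exist and why reporting uses midpoints
(below). (ii) is what makes the stability analysis sound.

## Bounding stable states of large models

Exhaustive attractor enumeration (`qn_attractors()`) is the ground truth but
dies combinatorially (the bundled 44-node model has $\sim 10^{21}$ states).
For large models `qn_stable_bounds()` instead maintains one interval per node
and iterates to a greatest fixpoint: compute the extremal target values
attainable over the current box — by monotone interval evaluation of the
expression, or by exhaustive enumeration of regulator level combinations when
an expression references the same regulator twice and the sub-grid is small —
then shrink each interval to its intersection with
$[\lfloor T_{\min}\rfloor, \lceil T_{\max}\rceil]$, clamped to the node
range. Intervals never grow, so the sweep count is bounded by the sum of
range sizes.

The box is *sound*: every state of every attractor lies inside it (a node can
only rise into a level its target somewhere exceeded, and can only rest at a
level its target can reach; the floor/ceil widening accounts for the
move-by-one semantics). Tightness is best-effort. When all intervals collapse
to singletons the network provably has a unique attractor — a single fixed
point. When they do not, `qn_corner_attractors()` simulates from the two
extreme corners of the box; finding two distinct fixed points *certifies* a
bifurcation. Failure to find them proves nothing and is reported as "not
proven", never as "unique".

Reported levels follow the reporting rule used throughout the screens: a
proven fixed point reports the level itself; a loop or bifurcation reports
the midpoint of the node's limits, which for integer bounds is an exact
half-integer (`qn_reported_level()`).

## Perturbations, backgrounds, screens

Mutations and drugs are *target-function overrides*: a knockout replaces a
node's target with its minimum level, an activation with its maximum,
`set_level` with any constant, and a drug with one or more node-level
overrides (clamps or replacement expressions, e.g. a mutant-BRAF inhibitor
that strips the mutant input while leaving physiological activation intact).
Backgrounds are named clamp sets representing genotypes and transcriptional
states; they are applied before perturbations, and a perturbation aimed at a
background-clamped node deliberately wins (with a loud message) — otherwise a
drug could never act on a mutant node.

`qn_screen()` crosses backgrounds with perturbations (optionally all
unordered pairs), bounds the stable states of each cell, and reports each
readout. The *tumour growth score* of a row is proliferation minus apoptosis.
`qn_optimal_pairs()` implements the combination-selection rule: keep pairs
whose residency readout does not exceed the per-background baseline (i.e.
that do not enhance Langerhans-cell retention in the skin), rank by ascending
growth score; the pairs attaining the minimum are the optimal set. Whether
"optimal" should additionally require a minimum score reduction is left as
an explicit knob (`max_score`) rather than hard-coded; the default filter is
the literal residency criterion.

## Scoring against experiment tables

Literature readouts come at different precisions, so experiment records
support three expectation dialects: an absolute level, a containing range,
and a direction (increase / decrease / unchanged) relative to the
background-only baseline. Directions use strict inequalities on reported
(possibly midpoint) levels; ties count as unchanged. Scoring is per
measurement — one experiment may contribute several measurements — and a
failing or erroring record never aborts the run; it is recorded and counted.

One analysis choice matters here. `qn_run_experiment()` defaults to
`method = "auto"`: exhaustive enumeration when the state space has at most
$10^4$ states, interval bounds otherwise. Enumeration limits are exact where
bounds may be loose, and the synthetic experiment generator labels records
with enumeration-derived truth; using the same analysis on the same small
models keeps "100% by construction" an actual theorem rather than a hope.
Large models always go through the bounds engine, exactly as in the screens.

## What the synthetic generators emulate — and what they do not

`qn_random_network()` draws signed edges independently and uses default
functions everywhere: it emulates the *shape* of curated models (sparse,
signed, multi-level) and is the fodder for the property suite (oracle
containment, uniqueness agreement, determinism). It does not emulate their
biology: no motif structure, no explicit functions, no behaviour nodes.
Explicit-function coverage comes from the motifs and the bundled model.

`qn_motif("tnf_autocrine")` is the desk-scale analogue of an autocrine
positive feedback loop: ligand → receptor → transcription factor → ligand,
with a residency proxy inhibited by the ligand. Two nonlinearities are
essential. The receptor saturates (`min(max, 2*ligand)`) — half-maximal
ligand already signals fully — which removes the intermediate rest points
that plain averaging would leave. The transcription factor reinforces itself
(`max(receptor, self)`, as immediate-early factors such as cJUN induce their
own promoters) — without it, the synchronous update admits a rotating-wave
loop in which a pulse of activity chases around the ring forever; we verified
by enumeration that the plain ring has three attractors at range 0–2 and four
at 0–1, while the motif as shipped has exactly the two biologically meaningful
ones (all-off, all-on) at both settings. Clamping the ligand to its maximum
collapses the motif to the single "loop engaged" attractor.

`qn_synthetic_experiments()` samples random backgrounds and perturbations and
labels the records by the enumeration oracle, optionally corrupting a stated
fraction so that scoring must fail at exactly the corrupted measurements.
Because the labels come from the oracle, a passing validation suite certifies
the *engine*, not any biological claim.

## The bundled melanoma–LC model

`qn_melanoma_lc()` loads a 44-node / 50-edge *synthetic* reduced model of a
melanoma cell coupled to an epidermal Langerhans cell; it is written from
well-established signalling biology for demonstration and testing and is not
a transcription of any published curated model. Its mechanisms: MAPK
signalling with a `BRAF_V600E` input and an all-or-nothing Ets-1 switch
(`2*floor(ERK/2)`); TNF-α transcription requiring Sp1, Ets-1 and cJUN
jointly (`min` — the weakest factor gates the promoter); the autocrine
TNF → TNFR → JNK → cJUN → TNF loop with the saturating receptor; an
MITF-low state that makes cJUN constitutive (`max(JNK, 2 - MITF)`) and
thereby locks the loop on; PI3K/AKT released by PTEN loss; NFkB survival
signalling fed by both TNF receptor and AKT; p53 held down by MDM2;
CyclinD/CDK4/E2F opposed by p16^CDKN2A and p21; and an LC compartment where
TGF-β → SMAD3 → Id2 retains the cell in the epidermis against TNF- and
IL-1β-derived migration signals, with PI3K/AKT and MAPK branches feeding LC
survival and proliferation. `Residency_LC` uses range 0–4 so that the
distinct regimes (healthy 4, tumour loop-off 3, loop-on 1, TGF-β-blocked 0)
are integer levels of one node.

Under the five bundled backgrounds the model reproduces the qualitative
regimes it was built to show: the healthy control is a proven-unique fixed
point with no TNF and maximal residency; both MITF-high tumour backgrounds
are bistable (bounds not unique; the two box corners converge to TNF-off and
TNF-on fixed points) independent of PTEN status; both MITF-low backgrounds
are locked into the TNF-producing state. In the drug screen the three
TGF-β-pathway inhibitors and the Id2 inhibitor are the only treatments that
lower residency in *every* background, because they act on the LC-intrinsic
retention axis rather than on the tumour; MAPK inhibitors do the opposite
(they silence Ets-1, hence TNF, and retain LCs). In the pairwise screen the
minimum growth score is attained exactly by the two drug families that
complete each other: an IKK inhibitor plus a PI3K or AKT inhibitor (apoptosis
requires both survival arms down, and AKT loss also starves the
NFkB/AKT-dependent proliferation term), and an MDM2 inhibitor plus a CDK4 or
E2F inhibitor (p53-driven apoptosis plus a cell-cycle block). Pairs that
would match those scores by silencing TNF (MAPK inhibitor combinations) are
excluded by the residency filter — which is the point of the filter.

## Numerical and design choices

* Strict comparison in the update rule (`T > v` moves up even for
  `T = v + 1/2`); midpoint reporting absorbs the resulting 2-cycles.
* Cycle detection hashes full states along the trajectory (trajectories are
  short; transparency beats Floyd's algorithm when debugging a model).
* `qn_attractors()` refuses state spaces above $10^6$ states and points to
  the bounds engine; the property suites use networks of 4–6 nodes with
  ranges ≤ 2 (state spaces ≤ $10^4$, most ≤ 1000), 200 networks per run —
  sizes chosen so the full suite stays interactive while still covering both
  the unique and the bifurcating branches.
* Interval refinement widens with floor/ceil when intersecting; the grid
  fallback for repeated-regulator expressions caps at 4096 combinations
  (the bundled models stay far below it).
* Pairs in pairwise screens are unordered, self-pairs excluded, with
  canonical ordering by label; re-running any screen or CLI command with
  identical inputs is byte-identical (manifest timestamps go to logs, not
  artifacts).
* Knockout-then-overexpress of the same node is last-write-wins, documented
  in `?qn_apply`.

## Limitations

The semantics are synchronous only; asynchronous schedules (and their
nondeterminism) are out of scope. Division by non-constants and products of
two regulators are rejected by the grammar — that is what keeps interval
evaluation sound, but it also means genuinely multiplicative regulation must
be encoded with `min`/`avg` idioms. The bounds engine proves containment,
not attractor counts: for large models, multistability is certified only
when corner simulation happens to exhibit two attractors. And passing tests
on synthetic data certify engine correctness, not the biological fidelity of
any particular model encoded with it.
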