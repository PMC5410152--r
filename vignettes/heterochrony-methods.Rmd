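---
title: "Detecting heterochrony in developmental sequences: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterochrony in developmental sequences: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterochron)
```

## The problem

A developmental sequence records the *order* in which embryological
events occur in a species — not their absolute timing.  Comparing such
sequences across a clade asks two things: whether the orderings carry
phylogenetic signal (can they recover the tree?), and where along a
reference phylogeny individual events moved earlier or later
(*heterochrony*).  Both questions are complicated by three properties
of real data: sequences of different species resolve different numbers
of distinct stages; events can be tied (simultaneous at the recorded
resolution); and cells can be unknown (`?`) or structurally
inapplicable (`-`, e.g. limb events in limbless taxa).

This vignette explains the models implemented here, the tunable
parameters, the numerical choices, and what the simulation-based tests
do and do not establish.

## Encodings

**Continuous scaling** (`to_continuous`).  Within a species, recorded
positions are collapsed to ranks $1..P$ (ties share a rank) and mapped
to $(r-1)/(P-1)$, so the first event is 0 and the last is 1.  Scaling by
*distinct ranks* rather than raw stage numbers makes the encoding
invariant under any strictly monotone relabelling of stages — sources
that number stages differently yield identical characters (a property
test enforces this).  Unknown events are excluded from the ranking, so
`?` cells do not displace the values of recorded events.  A species with
fewer than two distinct positions carries no ordering information and
becomes all-unknown with a warning.

**Decile binning** (`discretize`).  States are `floor(10·v)` with
$v = 1$ clamped into state 9.  The published rule names the bins
"0–0.09 → 0, 0.1–0.19 → 1, …", which leaves the sliver $[0.09, 0.10)$
formally unassigned; `floor` joins it to bin 0, the simplest rule
consistent with both quoted bins.  The resulting characters are ordered
(additive) by construction since the states are a discretised magnitude.

**Event-pair coding** (`event_pair_encode`).  One character per
unordered pair $(i, j)$, $i < j$ in the fixed event numbering, with
state 0/1/2 for earlier/simultaneous/later.  The orientation convention
(state 2 ⇔ event $i$ later) fixes the sign of every downstream cracking
magnitude, so it is stated once here and never varied.  A pair is `?`
if either member is unknown and `-` if either is inapplicable (the
inapplicable marker wins when both apply, matching how limb pairs are
coded in limbless taxa).

## Parsimony

Lengths are computed by Fitch state-set union/intersection (unordered)
or Sankoff dynamic programming with cost $|a-b|$ (ordered), in compiled
code; both treat `?` and `-` as full ambiguity, which is how standard
parsimony software scores non-applicable cells.  Per-character minima
$m_i$ and star-tree maxima $g_i$ give the ensemble consistency and
retention indices.  Lengths are invariant under rerooting (tested), so
trees are scored as unrooted objects and rooted only for reporting.

The heuristic search is the classic two-phase strategy: random-addition
Wagner building (each taxon inserted on the edge minimising total
length; insertion ties broken by the seeded addition order, which makes
runs reproducible) followed by full tree bisection–reconnection
sweeps, keeping up to `hold` equally parsimonious trees per replicate
(defaults: 10 replicates, hold 10).  On eight-taxon problems the search
recovers the exhaustive-enumeration optimum in ≥95% of random matrices
(acceptance test); exhaustive enumeration itself (10,395 topologies at
8 tips) is available as `exhaustive_search` for ground truth.  MPT
*counts* depend on tie-breaking and buffer semantics of the particular
search implementation and are reported but never asserted.

The Templeton test ranks per-character length differences between two
topologies, drops zeros, and uses average ranks for ties.  For $n \le
25$ nonzero differences the two-tailed p comes from exact enumeration of
the $2^n$ sign-flip null — implemented by integer convolution over
doubled ranks so tied (half-integer) average ranks remain exact — and
matches full enumeration to machine precision for $n \le 12$ in the
tests.  Larger $n$ falls back to the normal approximation with tie and
continuity corrections.  When every difference is zero the test is
degenerate and reports p = 1 with a flag.

## Ancestral reconstruction

**Squared-change parsimony.**  Internal values minimise
$\sum_b (x_{parent(b)} - x_{child(b)})^2 / \ell_b$; with all
$\ell_b = 1$ this is the unweighted criterion, mirroring the equal
branch length (= 1) analyses; with calibrated lengths it is the
weighted criterion.  The minimiser solves the sparse stationarity
system exactly, and the minimised criterion is the character's "steps"
on the tree.  The solution coincides with the joint ML ancestral states
under Brownian motion, so the root equals the contrasts (GLS) estimate —
both facts are used as cross-checks in the tests (generic numerical
minimiser agreement within 1e−8; root identity with `pic_root_ci`).
Zero-length branches make the weighted criterion singular and are a
hard error directing the user to calibrate or use unit lengths.

**Root confidence intervals.**  The Felsenstein pruning recursion gives
the root estimate and its residual variance $v_{root}$; the Brownian
rate is $\hat\sigma^2 = \sum c_k^2 / \nu$ over the standardised
contrasts.  The default degrees of freedom are $\nu = n - 1$ (the
number of contrasts); the $n-2$ convention used by some contrast
software is selectable (`df = "n-2"`).  The 95% interval is
$\hat x_0 \pm t_{\nu,0.975}\sqrt{\hat\sigma^2 v_{root}}$.  Coverage is
95% ± 2% under Brownian simulation at 1000 replicates (acceptance
test).  A taxon value strictly outside the interval is flagged
*earlier*/*later*; with long branches the interval widens and flags
become rarer, which is the expected behaviour of the criterion rather
than a defect.  The `reference = "squamate"` mode prunes the outgroup
before reconstruction so flags are read against the ancestral ingroup
node.

**Mk maximum likelihood.**  One-rate symmetric Markov model per
character, with the state space equal to the character's *observed*
alphabet — using the global 0–9 alphabet would park probability mass on
never-observed states, and event-pair characters are naturally 3-state.
The equal-rates transition matrix has the closed form
$P_{ii}(t) = 1/k + (k-1)e^{-krt}/k$, so no numerical matrix exponential
is needed.  The rate is optimised on the log scale within
$[10^{-8}, 100]$ (a warning reports optimiser-at-bound, which happens
for saturated characters whose likelihood is flat in the rate);
marginal node probabilities combine down-pass and up-pass partials,
equivalent to rerooting at each node, and match brute-force summation
within 1e−9 on four-tip trees.

## Branch changes and event-pair cracking

For parsimony reconstructions the package computes full MPR state sets
(the states a node takes in at least one most-parsimonious
reconstruction) from a Sankoff down/up pass.  A branch is listed as
carrying a change only when the parent and child sets are **disjoint** —
equivalently, the change occurs in *every* most-parsimonious
reconstruction, hence under both ACCTRAN and DELTRAN.  This is the
conservative reading; an optional outgroup polarisation constrains the
root to the outgroup's state when that state is itself
most-parsimonious, which resolves the classic
outgroup-vs-ingroup ambiguity on three-taxon statements.

Cracking converts a node's changed pairs into per-event scores.  With
ordered semantics the magnitude of a change is (child − parent); a
set-valued endpoint whose consistent values all point one way takes the
mean (0 → {1,2} gives 1.5), while endpoints straddling both directions
(1 → {0,2}) are excluded as direction-ambiguous.  A node is crackable
only when at least one event joins two or more non-excluded changes:
one synapomorphy, or two involving four different events, cannot
separate the moving event from its partners.  Each change of pair
$(i,j)$ with magnitude $m$ adds $+m$ to event $i$ and $-m$ to event $j$
(positive = later), and an event's TRC is its summed contribution
divided by $n_e$, the number of changed pairs it joins.  Both the
normalisation and the interval are deliberately isolated choices: the
divisor could alternatively be the number of all scorable pairs, and
the source literature does not restate its exact recipe, so `crack_node`
keeps the rule in one place.  The 95% interval is the Student-t CI *of
the mean* of the participating events' TRCs, and flags use strict
inequality ("beyond the interval").  A conservation audit (each change
enters exactly two tallies with opposite signs) and listing-order
invariance are property-tested.

## The simulator and what the tests show

`simulate_timelines` evolves the identity event order along a tree:
each branch receives Poisson(swap rate × length) random *adjacent
transpositions* (a Kendall-walk, the minimal neutral model of sequence
churn), then any injected shifts — an event moved by a stated signed
number of positions, clamped at the ends — and tips are optionally
corrupted with ties, missing cells and inapplicable limb events.  The
truth log records every event's net rank displacement per branch.

Defaults mirror the study conditions the package targets: 20 events ×
29 species for encoding checks; 12 taxa × 10 events, swap rate 0.5 per
unit branch, one +4-position shift, 50 seeded replicates for the
recovery benchmark.  Under those conditions the continuous root-CI
criterion recovers the injected (taxon, event, direction) in ~100% of
replicates; event-pair cracking recovers it in ~78%.  The cracking
misses are structural: when a background transposition happens to move
the target event before the shift is applied, the realised displacement
drops to three positions, only four events participate in the crack,
and the t-interval over TRCs {+2, −2, −2, −2} (upper bound 2.18) just
covers the +2 outlier that the five-event case (upper bound 1.02) would
flag.  That is the documented conservative criterion, not a tuning
artefact, and the benchmark seeds are fixed.

What passing these tests does **not** show: the simulator's neutral
model is adjacent-transposition churn with independent cells, while
real organogenesis data have correlated modules, systematic missingness
(early embryos under-observed), and stage-resolution differences
between sources; recovery rates on real matrices can be lower.  The
simulator also models no absolute time, only order.

## Fossil calibration

`calibrate_branch_lengths` fixes calibrated nodes (the MRCA of each
calibration's tip set, so one table serves both hypothesis topologies)
at their oldest total-group fossil age exactly, ages extant tips at 0,
and ages every uncalibrated node bottom-up at +3 Ma per branch above
its oldest-aged child — the "arbitrary 3" convention for branches
without fossil information (the bundled lepidosaur table derives the
Iguania node as 99 + 3 + 3 = 105 Ma this way).  Branch lengths are age
differences, so the output is ultrametric and calibrated ages are never
smoothed.  Two deliberate behaviours: calibrations resolving to a
single sampled tip (stem calibrations, e.g. a clade sampled by one
species) are skipped with a warning rather than guessed onto a branch;
and a calibrated node not strictly older than a descendant's assigned
age is a hard error naming the pair — surfacing, rather than silently
adjusting, cases where two calibrations sit closer than the +3 steps
allow.

## Problem sizes and reproducibility

The shipped tests run the full stack at deliberately modest sizes —
exhaustive parsimony oracles at ≤6 taxa (and 10,395-topology
enumeration at 8), 1000-replicate coverage simulation at 20 tips, the
50-replicate recovery benchmark at 12 × 10 — chosen so the whole suite
completes in a few minutes while still exercising every code path;
all stochastic tests fix their seeds.  `scripts/acceptance.R` re-derives
the headline numbers from scratch under a caller-supplied seed.
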