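---
title: "Depth-first enumeration of elementary flux modes by linear programming"
author: "efmdfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-first enumeration of elementary flux modes by linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmdfs)
```

## The model

A metabolic network is a stoichiometric matrix $S$ with $M$ internal
metabolites (rows) and $R$ irreversible reactions (columns).  Reversible
reactions are first decomposed into opposing irreversible pairs
(`split_reversible()`), so the steady-state flux space is the polyhedral cone

$$ C = \{\, v \in \mathbb{R}^R : S v = 0,\; v \ge 0 \,\}. $$

An *elementary flux mode* (EFM) is a support-minimal nonzero element of $C$,
unique up to positive scaling.  The classical rank test calls $v$ elementary
when the column submatrix over its active reactions
$\bar Z(v) = \{i : v_i \ne 0\}$ has nullity one,

$$ \operatorname{nullity} S_{*,\bar Z(v)} = |\bar Z(v)| -
   \operatorname{rank} S_{*,\bar Z(v)} = 1, $$

with the one-dimensional kernel signable positive on the support
(`is_elementary()`).

Writing $\mathrm{DoF} = \operatorname{nullity}(S) = R - \operatorname{rank}(S)$
for the degrees of freedom, an equivalent characterization drives this
package: **an EFM has exactly $\mathrm{DoF}-1$ independent inactive free
fluxes**.  Every flux vector is $v = NS \cdot t$ for a nullspace basis $NS$
($R \times \mathrm{DoF}$) and coefficients $t$; pinning $\mathrm{DoF}-1$
independent rows of $NS$ to zero leaves a one-dimensional solution line, and
when that line meets the cone nontrivially its ray is elementary.  Choosing,
for each EFM, the *leading* (smallest-index) set of $\mathrm{DoF}-1$
independent inactive reactions makes the identification unique, which is the
property the depth-first search exploits.  The package verifies this
uniqueness empirically (distinctness and leading-ness of all emitted
identification sets are asserted in the test suite) rather than assuming it.

## The nullspace basis

`nullspace_basis()` computes $NS_{\mathrm{rref}}$: the reduced-row-echelon
form of a nullspace basis in which the rows of the $\mathrm{DoF}$ leading
independent reactions (the *pivot rows*, scanned in ascending index order)
form the identity matrix.  Consequently $t$ equals the pivot-reaction fluxes
and $t \ge 0$ on the cone.  The float RREF runs with partial pivoting and the
pivot rows are snapped exactly to $\{0,1\}$ afterwards.

Rank queries use a singular-value decomposition with relative tolerance
$10^{-10}$ times the largest column norm.  SVD was chosen deliberately: R's
LINPACK QR rank estimate misjudges matrices containing exactly-zero columns,
which arise routinely here (nullspace rows of blocked reactions).  The
tolerance scale is floored at one because every matrix ranked in this
package — integer stoichiometries, unit-pivot bases — has natural scale
$\ge 1$; without the floor, a numerically-zero row would rank as 1 against
its own rounding error.

`sparse_efm_basis()` builds the alternative basis $NS_{\mathrm{EFM}}$ whose
columns are short EFMs: for each pivot reaction $j$ in turn it solves the LP
$\min \sum_i v_i$ s.t. $S v = 0$, $v \ge 0$, $v_j = 1$ — a vertex of this
polyhedron is elementary — and keeps vertices that increase the rank of the
accumulating basis.  Columns that cannot be avoided taking negative
coefficients (detected per column by LP feasibility of $NS\,t \ge 0$,
$t_c \le -1$) are flagged `sign_free_columns`; when fewer than
$\mathrm{DoF}$ independent short modes exist (possible when the cone does
not span the nullspace) the RREF basis is returned with a warning.

## Feasibility testing

Constraint configurations are tested by a blank-objective LP over $t$
(`lp_feasible()`): $NS\,t = 0$ on inactive rows (IFF), $NS\,t \ge 1$ on
active rows (FAF), $NS\,t \ge k$ for explicit flux bounds, $NS\,t \ge 0$
elsewhere.  Strict positivity is encoded as $\ge 1$: the feasible set is a
cone, so any strictly positive solution rescales to clear the bound.  The
same argument lets a constrained mode be reported in its canonical scaling
(smallest positive entry equal to one).

Two interchangeable backends answer these queries so correctness is never
tied to one solver:

* `"simplex"` (default) — a dense two-phase primal simplex with Bland's
  anti-cycling rule, written for this package.  The LPs are tiny (tens of
  rows, $\mathrm{DoF}$ structural variables) but solved many thousands of
  times per run, so the tableau operations are vectorized.
* `"quadprog"` — feasibility via the strictly convex QP
  $\min \tfrac12\|t\|^2$ under the same constraints (`quadprog::solve.QP`
  fails exactly when the constraints are inconsistent), an algorithmically
  independent route used for cross-checks.

The test suite additionally validates feasibility answers against a purely
combinatorial oracle: a configuration $\{v_{\mathrm{iff}}=0,\,
v_{\mathrm{faf}}>0\}$ is feasible iff every FAF reaction is active in some
enumerated mode whose support avoids the IFF set.

`forced_active()` is flux variability analysis reduced to the question the
search actually asks: a reaction is dependently active iff forcing it to
zero destroys feasibility (one LP per candidate, about half the work of
min/max FVA; the classical minimum-based variant is available via
`method = "fva"`).

## The depth-first search

`enumerate_efms()` maintains an ordered IFF list, a FAF list, and the
recording matrix $M_{\mathrm{record}}$ ($R \times (\mathrm{DoF}-1)$, column
$j$ marking reactions forced active by the $j$-th IFF).

* **Initialization** presets the IFF list to the leading $\mathrm{DoF}-1$
  pivot rows and scans reactions past the terminal IFF as lone FAF
  candidates, one at a time; the first feasible candidate certifies the
  initial EFM.
* **Backtracking** pops the terminal IFF $j$, clears its recording column,
  drops all FAF with index above $j$, adds $j$ to the FAF list and tests
  feasibility; on success forward-tracking resumes at cursor $j$, otherwise
  the next IFF is popped.  When the IFF list empties without a feasible
  configuration the search makes one final forward pass and terminates when
  that pass fails the second check-point.
* **Forward-tracking** scans reactions above the cursor, skipping FAF
  members and $M_{\mathrm{record}}$-marked reactions.  A candidate joins the
  IFF list iff its nullspace row increases the rank of the IFF rows
  (`rank_adds()` — a zero constraint on a dependent row would not shrink the
  solution space) *and* the extended configuration stays feasible.  On
  joining, its recording column is set by `forced_active()` over the
  still-unresolved reactions.  At $\mathrm{DoF}-1$ IFF the solution line's
  ray is emitted and the search turns back.

Three progress check-points run before each extension: (1) enough
candidates must remain to reach $\mathrm{DoF}-1$ IFF; (2) the IFF rows plus
candidate rows must still span $\mathrm{DoF}-1$ dimensions; (3) the column
submatrix over the forced-active reactions ($M_{\mathrm{record}}$ marks plus
FAF) must have nullity zero.  Nullity one at check-point 3 is the early
exit: the branch's only possible mode is the kernel ray of that submatrix.
The ray is materialized directly from the kernel, checked against the
constraint set (scalably: zero pattern, positivity, basis-coefficient
signs), completed to its leading identification set, and emitted.  Nullity
two or more proves no elementary mode exists down the branch — any deeper
support would contain the current forced-active set, and its kernel would
then extend a kernel vector by zeros, contradicting support-minimality — so
the branch is pruned.

Two behaviors here were genuinely open design choices:

* **Early-exit materialization.** The kernel ray, not the LP's feasible
  point, is used: with two or more FAF constraints an LP vertex can be a
  conic mix of several modes, whereas the nullity-one kernel is the unique
  candidate.
* **Early-exit re-finds.** The leading-IFF uniqueness argument covers
  full-depth identifications; the early exit can re-find a mode already
  emitted from another subtree.  Re-finds are detected by a support hash
  and suppressed silently (counted in
  `counters$duplicates_suppressed`); a duplicate between two *full-depth*
  emissions would be a genuine bug and raises an error when
  `check_duplicates = TRUE`.  The hash table grows with the number of
  modes; it is the one bookkeeping structure that is not constant-size, and
  callers that must avoid it can disable duplicate checking (the flux
  record buffer itself stays bounded by `batch_size` regardless).

Emission is streamed: records accumulate in a buffer of at most
`batch_size` rows (default 10,000) and are flushed to a caller-provided
sink together with a resumable snapshot (IFF, FAF, cursor, phase).  On
resume the recording matrix is recomputed; column $j$ may only assume the
FAF entries below `iff[j]`, because later FAF additions are cleared again
during backtracking and marks conditioned on them would over-prune.

## Partitioning into exclusive sub-jobs

`partition_jobs()` fixes each chosen basis column to *inactive*
($t_j = 0$) or *active* ($t_j \ge 1$), producing $2^k$ descriptors.  With
the RREF basis $t_j$ is the $j$-th pivot reaction's flux, so the cells
partition the EFM set exactly by pivot activity pattern, and the union of
sub-job outputs provably equals the unpartitioned run — `merge_jobs()`
verifies pairwise support disjointness and hard-errors on overlap.  For an
$NS_{\mathrm{EFM}}$ basis only the sign-free columns are offered by
default; a mode whose coefficient on a constrained sign-free column is
negative falls in neither cell, so sign-free splits are exhaustive only
when no such mode exists — the merge-time verification and the
fixture tests are the guard.  Descriptors are plain JSON files
(`write_jobs()`), so any scheduler or a shell loop can dispatch them; jobs
can be interrupted, resumed, or subdivided further via the snapshot
mechanism.

## Compression and model reduction

`compress_network()` iterates to a fixed point over: blocked-reaction
removal (per-reaction LP maximization with all fluxes capped at $10^6$ so
maxima are finite, zero tolerance $10^{-9}$), enzyme-subset lumping
(reactions whose nullspace rows are proportional with positive ratio carry
proportional flux in every steady state and are merged with recorded
ratios), optional duplicate-column merging, and removal of all-zero
metabolite rows.  The first two steps and the row cleanup preserve EFM
counts one-to-one under `expand_efms()`.  Duplicate merging does *not*:
two modes differing only in the choice among duplicated reactions collapse
into one compressed mode.  It is therefore off by default, and the
expansion of a merged group routes flux through its representative member.
A fully lumped route can leave an all-zero column (an exchange-to-exchange
reaction with no internal metabolites left); compressed networks are
allowed to carry such columns.

`fva_reduce()` implements the genome-scale reduction recipe: fix the
substrate uptake to one unit, pin the objective at its LP maximum, and
retain exactly the reactions whose flux variability interval is nonzero
(per-reaction capped LP min/max, tolerance $10^{-9}$).  The output is a
column subset of the input and the operation is idempotent.
`replace_with_drains()` decomposes a composite (biomass-style) equation
into unit drains per consumed metabolite, the step that lets biomass
composition be varied by constraining drain subsets.

## Fixtures, the synthetic toy network, and the generator

`fixture_chain()` (one mode) and `fixture_diamond()` (two modes) are the
smallest meaningful cases.  `fixture_toy()` is a **synthetic** 14-reaction,
8-metabolite worked example constructed for this package as a branched
uptake-to-drain conversion network.  It was built to exhibit a specific
published summary profile — $M = 8$, $R = 14$, $\mathrm{DoF} = 6$, exactly
9 EFMs, and the forced-activity relation "R01 active with R02 silenced
forces R04" — but its wiring is this package's own construction, not a
transcription of any published figure, and no result obtained on it should
be read as a reproduction of numbers from an external network.

`random_network()` emulates the combinatorial shape of small metabolic
models: sparse integer stoichiometry in $\{-2,-1,1,2\}$, at least one pure
source and one pure sink, pairwise non-proportional columns (duplicate
reactions are excluded deliberately so that compression round-trips are
exactly count-preserving), and a guaranteed nonzero steady-state flux
(LP-checked, redrawn up to a retry cap).  It does **not** emulate
reversible-pair structure, conservation pools, or realistic pathway length
distributions, so passing the randomized suites demonstrates combinatorial
and numerical correctness of the enumeration machinery — not biological
fidelity on genome-scale reconstructions.  Genome-scale inputs also bring
numerical regimes (poorly scaled coefficients, degenerate LPs) that the
desk-scale suites do not probe.

## Problem sizes and tolerances

The verification suites run at sizes where the brute-force oracle
(`brute_force_efms()`, all $\binom{R}{\mathrm{DoF}-1}$ subsets, guarded at
$10^7$ combinations) is exact and fast: 100 seeded random networks with
$R \le 20$ and $\mathrm{DoF} \le 6$ for search/oracle equality, 20 fixtures
for partition and constraint checks, a 64-mode ladder network for the
bounded-buffer check.  These sizes were chosen as the smallest that
exercise every code path — early exits, pruning at both check-points,
forced-active marking, multi-level backtracking — while keeping the whole
suite interactive.

Numerical defaults: support zero tolerance $10^{-9}$ (relative to the
largest flux entry), rank tolerance $10^{-10}$ (relative, floored scale),
LP pivot tolerance $10^{-9}$, flux cap $10^6$ for boundedness-only LPs.
Ties in the row-sorting heuristic (`sort_rows_heuristic()`, ascending
product of positive and negative row counts) break by original index, so
the permutation is stable and reproducible.

## Known limitations

* Exhaustive enumeration is exponential in $\mathrm{DoF}$; this
  implementation is a correct, fully-tested desk-scale tool, not a tuned
  cluster code.  The LP engine is pure R; swapping in a compiled solver
  behind the backend contract is the first thing to do for larger models.
* Sign-free column splits of an $NS_{\mathrm{EFM}}$ basis are verified
  exclusive but not guaranteed exhaustive (negative-coefficient cells are
  not enumerated); RREF-pivot splits are exact.
* The duplicate-suppression hash scales with the number of modes (see
  above).
* SBML import covers Level 3 core stoichiometry (species, reactions,
  boundary conditions); gene–protein–reaction rules, compartments and flux
  bound annotations are ignored.
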