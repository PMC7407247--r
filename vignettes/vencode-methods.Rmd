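---
title: "Methods: intersectional RE codes, their discovery and their scores"
author: "VEnCodeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intersectional RE codes, their discovery and their scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VEnCodeR)
```

# The model

A regulatory-element (RE) activity atlas is an `r` x `n` matrix of TPM
values: rows are promoters or enhancers, columns are samples labelled
"cell type, donor". A **VEnCode** for a target cell type is a set of `k`
REs that are all active in the target while, in every other cell type, at
least one member is inactive. Biologically this is a multiple-input AND
gate: a construct sensing the k activities fires only in cells where they
intersect, which — if the code is exclusive — is the target cell type
alone.

The exclusivity condition over a binarized landscape is a Boolean formula
whose truth table has `2^(c*k)` rows, and the combination space is
`C(r, k)`; both are computed by `truthTableRows()` and
`combinationSpace()` on the log scale so atlas-sized inputs do not
overflow. Exhaustive search is hopeless at atlas scale, which motivates
the binarization filters and the two heuristics below.

# Binarization (`binarizeForTarget`)

Calls are deliberately asymmetric and conservative:

* **Target activity** uses the **minimum** over the target's donors: an RE
  must exceed the activity threshold in *every* donor (the "intersection
  of donors" rule), and must exceed the nonzero prefilter (default 0 TPM)
  in every donor even to be retained. This biases the candidate pool
  toward REs that are reliably on in the target.
* **Non-target activity** uses the **donor mean**: a cell type is called
  active for an RE iff the mean TPM of its donors exceeds the inactivity
  threshold. Collapsing donors here (arithmetic mean of raw TPM, never of
  binarized calls) shrinks the database by the mean donors-per-cell-type
  factor (~3.5 for a curated 154-type, 537-sample atlas).

Default thresholds are the most selective settings for each RE class:
activity 0.5 TPM for promoters and 0.1 TPM for enhancers, inactivity 0 TPM
for both. All comparisons are strict (">", thresholds must be exceeded);
`thresholdConfig(strict = FALSE)` switches to ">=" for dialects that call
"at or above".

## The sparsity pre-filter and its direction

`sparsityFilter()` removes REs active in more than X% of the *non-target*
cell types (the target column is active by construction and is excluded
from the denominator so it cannot bias X). X starts at 90. The published
procedure then *decrements* X by 5 units whenever fewer than `k` REs
survive — but decrementing makes the filter stricter and can only remove
more REs, while the trigger ("not enough REs left") calls for relaxation.
The two halves of that rule pull in opposite directions, so the package
implements the literal decrement as the default and exposes
`sparsityDirection = "increment"` as the reading that can actually recover
`k` REs; with the default direction an unsatisfiable start is reported as
an explicit error rather than silently looping.

# Search methods

## Sampling (`sampleVEnCodes`)

Uniform random k-subsets of the filtered candidate pool are tested against
the exclusivity predicate and deduplicated (a code is an unordered set).
When the requested budget covers the whole combination space
(`nSamples >= choose(r, k)`), rejection sampling is strictly dominated by
systematic enumeration, so the implementation enumerates; this also makes
"sampling at exhaustive budget" reproduce the brute-force valid set
exactly, which the test suite exploits as an oracle check.

## Greedy sparseness-ordered tree (`heuristicVEnCodes`)

REs are sorted by **sparseness** — the number of non-target cell types in
which they are active, ties broken lexicographically by id for
determinism. The sparsest RE becomes the first node. The cell types in
which all current node REs are co-active are the **problematic** columns;
columns already blocked are culled. At each node the search:

1. scans for single REs inactive in *every* remaining problematic column —
   each completes a valid code; the `neighbors = 3` nearest such REs in
   sparseness order are taken, so one node can yield several codes;
2. failing that, re-sorts the remaining REs by sparseness *within the
   problematic columns* and opens deeper nodes, to depth at most `k`.

A partial combination that is already exclusive with fewer than `k` REs is
padded with the next sparsest target-active REs: any superset of an
exclusive set drawn from target-active REs is itself exclusive
(monotonicity in `k`), so padding only adds safety.

`nodesPerLevel = 3` nodes are opened eagerly per level. During
development, bounding each level *hard* at 3 proved brittle: within
problematic columns the sparseness counts are heavily tied, and on
tie-dense landscapes the one useful sibling regularly sits just past the
cap, making the search abandon landscapes whose unique valid code it can
provably reach. Since the search is meant to test several nodes at each
level *before giving up*, the default (`backtrack = TRUE`) continues with
further siblings in sparseness order while the result quota (default 20
distinct codes) is unmet, bounded by a global `maxNodes` budget. Setting
`backtrack = FALSE` restores the strict 3-node greedy.

## Mixed-class codes (`heuristic2VEnCodes`)

Enhancers make the better synthetic drivers but are sparse and noisy;
promoters are reliable but less specific. `heuristic2` takes the `k1`
sparsest target-active enhancers; if they are already exclusive, done
(minimal code by default; `padToFixed` appends promoters only on request,
since both minimal-size and fixed-size reporting are useful). Otherwise
the problematic columns — where all `k1` enhancers are co-active — are
handed to the greedy heuristic on the *promoter* landscape restricted to
those columns, which finds `k2` promoters blocking them. The combined
enhancer + promoter intersection is then exclusive; every emitted code is
re-verified against the merged landscape.

# Quality scores

## Intraindividual robustness E

Database false negatives (an RE recorded inactive that is really active)
are the dominant failure mode of a code. `eRaw()` simulates them: flip a
uniformly chosen currently-inactive entry of the code's `k x (c-1)`
non-target submatrix to active, one at a time, until the code stops being
exclusive; `E_raw` is the mean flip count over `nSims` simulations.

*Flip universe.* Flips outside the code's own submatrix can never change
its validity, so they are not simulated. The restriction rescales `E_raw`
identically for a code and for its best-case reference, hence the
normalized `E` is unaffected while simulations shrink by orders of
magnitude.

*Implementation.* Choosing uniformly among currently-inactive entries
without repetition is equivalent to flipping the initially-inactive
entries in a uniformly random order; each simulation therefore draws one
permutation and reads off the first time any column's inactive entries are
exhausted. The test suite checks the estimator against an exact
inclusion–exclusion enumeration of the same expectation on all instances
with `k*(c-1) <= 12`.

`E_best(c, k)` is `E_raw` for a best-case code (all `k` REs inactive in
every non-target cell type), memoized per `(c, k, nSims, seed)`, and
`E = 100 * E_raw / E_best`. Best-case codes score 100 up to Monte-Carlo
error; values slightly above 100 are reported as-is with a warning —
clamping would bias rank comparisons. `nSims` defaults to 2000 with the
per-score standard error available via `eStandardError()`; the choice
balances a ~1% relative SE against runtime.

For independent per-RE false-activation probability `p`, a best-case code
falsely fires in a given non-target cell with probability `p^k` — each
extra intersection multiplies the leakage down. The suite verifies the
closed form by simulation for `p` in {0.1, 0.3}, `k <= 4`.

## Interindividual robustness z

`donorHoldOutZ()` rebuilds the landscape from a subset of the target's
donors, generates codes from it, and checks each code against every
held-out donor's raw profile (a donor satisfies a code iff all `k` REs
exceed the activity threshold in that donor). `z` is the percentage of
codes valid on *all* held-out donors, averaged over all training subsets
of the requested size. Codes built from more donors are more robust: the
per-donor minimum rule then weeds out flaky REs before they enter a code.
A training subset from which no code can be generated contributes NA and
is excluded from the mean, with a warning when that holds for every
subset.

# Cross-validation conventions

External RE call sets (DNase, ATAC-seq, STARR-seq, ChIP, ...) are compared
by genomic overlap: coordinates are 0-based half-open (BED convention),
any overlap strictly greater than 0 nucleotides counts, strand is ignored,
and "chr1" and "1" name the same chromosome (a configurable alias map
handles other dialects; genome-build mismatches are deliberately the
caller's responsibility and are not lifted over). BED/BroadPeak input goes
through rtracklayer when available. The interval index used internally is
behaviourally identical to a linear scan, which the test suite enforces
against a per-base oracle.

`validateCode()` reports how many of a code's REs have external support;
`restrictToValidated()` flips the order — search only pre-validated REs,
so every resulting code has validation fraction 1. For specificity,
`matchCodesAcrossDatabase()` asks how often codes "fire" (all REs
externally active) in each cell type of an independent collection, and
`specificityIndex()` divides the target hit rate by the mean non-target
hit rate; when no non-target cell is ever hit the index is infinite and
`Inf` is returned as a documented sentinel rather than an arbitrary large
number.

# Single-cell pooling

Per-cell "ON" RE sets from shallow single-cell assays are pooled by union
(`poolCells`; a minimum per-RE cell-support threshold `minCells` is
available, default 1 — the plain-union reading, since sparse true calls
are more valuable than their noise costs at small cell numbers). The
pooled profile is injected as a new single-donor cell-type column with ON
REs at a sentinel TPM of 10 — far above every default threshold, making
the binary-to-TPM bridge explicit and configurable — and OFF REs at 0.
Downstream search treats the column exactly like a bulk cell type; z is
undefined for it (single donor).

# The synthetic landscape generator

`generateLandscape()` emulates the structure the pipeline expects from a
curated CAGE-seq atlas: `c` cell types with 2–6 donors each, `r`
target-active candidate REs, background activity `Bernoulli(0.2)` per
RE x non-target cell type (a sparse-but-realistic default for curated
atlases), and active TPM values drawn log-normal(0, 1) shifted 0.5 above
zero so active entries clear the default activity threshold in every
donor.

Planted codes are valid by construction (the **alibi** pattern: every
non-target cell type gets at least one planted RE forced inactive). With
`uniquePlant = TRUE` each planted RE additionally becomes the *sole*
blocker of one dedicated "signature" non-target cell type, which makes the
planted set the unique valid code of size at most `k` before noise — the
property the recovery benchmarks rely on. Donor-level noise is added by
`corruptProfiles()` (independent false-negative zeroing and false-positive
sentinel activation).

What the generator does **not** emulate: FANTOM5's empirical TPM
marginals, correlated activity between developmentally related cell types,
batch and protocol effects, and donor-specific biology beyond independent
entry noise. Passing tests on synthetic data therefore demonstrate
algorithmic correctness — search soundness and completeness at small
scale, score calibration, hold-out logic — not biological performance on
real atlases.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for quick, repeatable runs:
oracle-equivalence checks use 50 landscapes with `c <= 8`, `r <= 15`,
`k <= 4` (where `C(r, k)` is enumerable); recovery benchmarks use 100
landscapes at `c = 12`, `r = 25`, `k = 3`; E calibration uses
`nSims = 2000` against exact enumeration up to 12 flippable entries;
leakage uses 2000 cell-observations per `(p, k)`. Ties are always broken
lexicographically by RE id; all stochastic steps take explicit seeds and
record them in their reports.

# Known limitations

* The greedy searches are incomplete by design; an empty report means "not
  found at this effort", not "does not exist". Roughly a tenth of real
  cell types are expected to yield no code even at large `k`.
* Exclusivity is judged against the cell types present in the matrix; a
  code may fire in cell types or states absent from the atlas.
* OR/NOT/NOR gate codes and TPM-magnitude-aware (non-binary) scoring are
  out of scope; the binarized E score ignores how close an entry sits to
  its threshold.
* `E` values are comparable across `(c, k)` by construction, but only
  within a fixed binarization configuration.
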