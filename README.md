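# VEnCodeR

Discovery, quality ranking, and cross-validation of **versatile entry codes
(VEnCodes)** — minimal combinations of *k* co-active regulatory elements
(REs) whose intersection is exclusive to one target cell type — from
CAGE-seq-style RE activity matrices such as the FANTOM5 promoter and
enhancer atlases.

## The problem

Most human cell types have no single promoter or enhancer that is active in
them and nowhere else. Intersectional ("AND"-gate) genetics works around
this: a synthetic construct fires only where *k* chosen REs are all active.
Given an RE-by-sample TPM matrix covering *c* cell types (each with several
donors), the task is to find, for a target cell type, a set of *k* REs such
that

* every RE exceeds the activity threshold in **all** donors of the target
  (the conservative "intersection of donors" rule), and
* in **every** other cell type at least one RE of the set is inactive
  (donor-mean TPM at or below the inactivity threshold).

The number of candidate combinations, `C(r, k)`, is astronomically large at
atlas scale (`C(201802, 4) ≈ 6.9e19`), so the package provides:

* **binarization** with class-specific thresholds (promoters 0.5 TPM,
  enhancers 0.1 TPM target activity; 0 TPM non-target inactivity) and a
  sparse-RE pre-filter,
* a **sampling** search (uniform random k-subsets; switches to systematic
  enumeration when the budget covers the whole combination space),
* a greedy **heuristic** search ordered by expression sparseness, with
  "problematic"-cell-type-driven node selection and backtracking,
* **heuristic2**, which mixes the k1 sparsest enhancers with k2 blocking
  promoters,
* the **E score**: Monte-Carlo false-negative robustness,
  `E = 100 * E_raw / E_best(c, k)`, where `E_raw` is the mean number of
  random inactive-to-active flips a code withstands before losing
  exclusivity and `E_best` is the same quantity for a best-case code,
* the **z score**: donor hold-out (interindividual) robustness — the
  percentage of codes derived from a donor subset that remain valid on
  every held-out donor,
* genomic-interval **cross-validation** against external RE call sets
  (DNase, ATAC-seq, STARR-seq, ...; any overlap > 0 nt counts),
* **single-cell pooling** (union of per-cell "ON" calls injected as a new
  cell type), and
* a **synthetic landscape generator** with planted, provably unique
  ground-truth codes for benchmarking every step without downloads.

## Worked example

```r
library(VEnCodeR)

# synthetic landscape: 10 cell types, 20 candidate REs, one planted k = 3
# code for the target
prof <- generateLandscape(10, 20,
                          planted = list(target = "hepatocyte-like", k = 3),
                          seed = 1)
land <- binarizeForTarget(prof, "hepatocyte-like")
land
#> BinaryLandscape for 'hepatocyte-like': r = 20 REs x c = 10 cell types
#>   mean non-target activity: 0.422

rep <- heuristicVEnCodes(land, 3)
rep
#> SearchReport: 1 VEnCode(s) for 'hepatocyte-like' by heuristic (k = 3, 249 iterations)

best <- topVEnCodes(rep, 3, land, nSims = 2000, seed = 2)
best[[1]]
#> VEnCode (k = 3, heuristic) for 'hepatocyte-like'
#>   REs: chr1:1000-1500, chr1:4000-4500, chr1:7000-7500
#>   E = 37.8

donorHoldOutZ(prof, "hepatocyte-like", trainSize = 1,
              method = "heuristic", k = 3, seed = 3)
#> RobustnessScore: z = 100.0% (2 codes, 2 train subset(s))
```

The search recovered the planted triple; its E of 37.8 says it withstands
about 38% as many random false-negative corrections as a best-case code of
the same dimensions would, and z = 100% says codes built from any single
donor stay valid on the held-out donors.

A file-based pipeline is available through the `vencode` script
(`inst/scripts/vencode`): `simulate`, `curate`, `binarize`, `sample`,
`heuristic`, `heuristic2`, `rank`, `zscore`, `crossval`, `pool-sc`.
Exit status 2 flags "no VEnCode exists under these settings" (a scientific
result), 1 an input error.

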