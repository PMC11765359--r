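---
title: "Reconstructing constant-weight strings from prefix-suffix compositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing constant-weight strings from prefix-suffix compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrecon)
```

## The observation model

A polymer-based storage channel synthesizes `h` molecules encoding binary
strings of a common length `n`, and readout reports, for every molecule and
every affix length `j`, only the *composition* of the length-`j` prefix and
of the length-`j` suffix: how many zeros and how many ones it contains.
Nothing links an observed composition to a molecule, to an end, or to the
other affixes of the same molecule. When the code is *constant weight* — all
strings carry the same number `w̄` of ones — the unordered pile of `2nh`
compositions gains strong symmetries, and this package implements
reconstruction under exactly that assumption.

Two losses of information are intrinsic. First, a string and its reversal
produce identical prefix-suffix compositions, so reconstruction can only ever
be up to reversal of each member; we work with *canonical classes*
(each member replaced by the lexicographic minimum of itself and its
reversal, then sorted — `canonical_class()`). Second, distinct multisets may
generate the same compositions; deciding when they cannot is the uniqueness
question.

## Grids, flows, and cumulative weight functions

All observed information is captured by the grid `a`, where `a[l, w]` counts
affixes of length `l` and weight `w` (`composition_multiset()`). For the
grid of a genuine constant-weight multiset:

* every row `l ≥ 1` sums to `2h` (each molecule contributes one prefix and
  one suffix per length);
* `a[l, w] = a[n − l, w̄ − w]` (a prefix of length `l` and weight `w` leaves
  a suffix of length `n − l` and weight `w̄ − w`);
* the *keep/drop flows* `b[l, w] = s[l−1, w] − s[l, w+1]` and
  `c[l, w] = s[l, w] − s[l−1, w]`, with `s[l, w] = Σ_{v ≥ w} a[l, v]`, are
  nonnegative; they count affixes whose weight stays or drops as the length
  shrinks by one, and `a = b + c`.

`validate_composition_multiset()` checks all of these and reports each
violation with a witness cell; all reconstruction entry points validate
eagerly and fail with that report, so a corrupted table never reaches the
solvers.

A *cumulative weight function* (CWF) assigns to each label `m ∈ [2h]` a
running weight profile: odd labels track prefixes of one string, even labels
its suffixes, with `f(0, m) = 0`, unit steps, and the rotational pairing
`f(l, 2j−1) + f(n−l, 2j) = w̄`. A CWF whose component functions pass through
each cell `(l, w)` exactly `a[l, w]` times is a *solution*; its odd-label
first differences are a compatible multiset. Solutions are closed under the
*swap* operation (`cwf_swap()`): exchanging two component functions on a
maximal interval of their discrepancy, together with the mirrored exchange of
their partner labels, yields another solution — this is the mechanism by
which ambiguity arises, and the basis of the uniqueness criterion.

## The three algorithms

**Greedy solver** (`reconstruct_one()`). Sweeping lengths `l = 1..n−1`, the
`k`-th odd label receives the unique weight `w` with
`s[l, w+1] < k ≤ s[l, w]` — larger weights go to smaller `k` — and even labels
are filled by the mirror rule `f(l, 2k) = w̄ − f(n−l, 2k−1)`. This runs in
O(nh) and always produces a solution for a valid grid. The construction is
followed by an explicit `is_solution()` assertion, so any defect would
surface as an error rather than a wrong answer.

**Uniqueness test** (`check_theorem1()`, `is_unique()`). The multiset behind
`M` is unique up to reversal exactly when one (equivalently, any) solution
CWF has at most two maximal discrepancy intervals between each label and its
partner and at most one between any other pair. `is_unique()` obtains the
greedy solution and applies the criterion; all violating pairs are reported,
not just the first, to aid diagnosis. The test suite verifies the verdict
against exhaustive enumeration on small universes.

**Complete enumerator** (`reconstruct_all()`). Constant weight makes a
solution determined by its behaviour on `0..⌊n/2⌋` plus a pairing of halves:

1. *Scan stage* (`scan_compositions()`). Labels are partitioned at the
   midpoint by median weight — sizes `a[n/2, w]` for even `n`, and
   `b[⌈n/2⌉, w]` / `c[⌈n/2⌉, w]` for odd `n` (`initial_partition()`) — and the
   sweep proceeds down to length 0. At each cell `(l, w)` the labels in each
   group split between "weight drops" and "weight keeps"; the admissible
   drop counts are the solutions of a bounded integer-composition equation
   with the group sizes as bounds (`bounded_compositions()`), and each
   solution spawns a branch. Groups are *label-oblivious*: only
   (size, half profile, doubled median) matter, which collapses the
   symmetric relabelings the problem does not distinguish. A leaf is a
   multiset of distinct half strings with multiplicities.
2. *Assembly stage* (`pairing_solutions()`, `assemble_pairing()`). Halves
   pair into full strings only when their median weights sum to `w̄`. For
   medians `w < w̄/2` the admissible pairings with median `w̄ − w` are the
   transportation matrices with the group sizes as margins; at `w = w̄/2`
   they are symmetric matrices with even diagonal. Every combination over
   all medians yields one compatible multiset; within a diagonal block the
   matching of labels is immaterial because all carry the same half profile,
   so pairs are formed first-fit.

Every assembled multiset is re-composed and checked against `M`, and the
classes are asserted pairwise distinct — the theory says duplicates cannot
occur, and the assertion converts any logic bug into a loud failure instead
of a silent wrong count.

### Numerical and tie-break choices

Medians are stored as doubled integers so that half-integer medians (odd
`n`) never meet floating point. Enumeration order is deterministic
throughout: cells are processed with `l` and `w` descending, bounded
compositions and transportation matrices in ascending lexicographic order,
output classes sorted by their serialized canonical form; re-runs are
byte-identical. `maximal_intervals(f, m, m)` returns an empty table rather
than erroring — the discrepancy of a function with itself is empty and the
callers treat it as such. Degenerate inputs (weight 0 or `n`, `h = 1`,
`n = 1`) pass through all code paths and are covered by tests.

The worst case of the enumeration is exponential (already the number of
compatible classes can be), so `scan_compositions()`, `pairing_solutions()`
and `reconstruct_all()` take a `max_states` cap (default `1e6` branches)
and fail with a clear message when exceeded; the command-line `reconstruct
--mode all` additionally refuses instances with `2h > 8` unless a cap or
`--force` is given.

## Synthetic data and the oracle

`random_instance(n, h, w, seed)` draws `h` independent uniformly random
weight-`w` strings by sampling `w` one-positions per string; with a seed it
is reproducible and restores the caller's RNG state. This emulates exactly
the study conditions of the reconstruction problem — error-free composition
readout of same-length, same-weight codewords. It does *not* emulate noisy
or missing compositions, non-constant-weight codebooks, or any sequence
correlation a real synthesis pipeline might introduce, so passing tests
demonstrate combinatorial correctness of the reconstruction, not robustness
to read errors (explicitly out of scope here).

`oracle_reconstruct_all()` is the independent ground truth: it enumerates
candidate multisets directly and never touches the CWF machinery. Pruning
(on by default) restricts candidates to strings whose own affix compositions
stay inside the support of the grid and abandons partial multisets whose
accumulated counts overshoot a cell; both reductions are sound, so the
pruned oracle remains exhaustive. `prune = FALSE` walks the full
combinations-with-repetition universe and is used where a literal full brute
force is wanted.

The central correctness property — enumerator output equals oracle output,
and the uniqueness verdict equals "exactly one class" — is tested
exhaustively over every constant-weight grid with `n ≤ 7`, `h ≤ 2` (all
weights) and on 200 seeded random instances with `n ≤ 10`, `h ≤ 3`. Those
problem sizes keep the whole suite around a minute on one core while still
covering every parity combination (even/odd `n`, half-weight medians,
palindromes, repeated strings); the greedy contract, swap closure, and the
grid/interval symmetries are property-tested on the same generators.

## Design decisions

* Dense `(n+1) × (n+1)` integer grids rather than sparse tables: `n` is
  small in every realistic decoding instance and dense indexing keeps the
  flow recursions one-liners.
* The corner cell `a[0,0] = 2h` is a convention synthesized on
  construction, never read from files; on-disk tables list `l ≥ 1` only.
* The common weight is inferred as the unique `w` with `a[n, w] = 2h`;
  ambiguity is impossible for a valid grid and raises an error otherwise.
* Reversal equivalence is *operationalized* as equality of canonical
  multisets. For palindromes the bookkeeping of "multiplicity of `t` and of
  its reversal" could be read two ways; both agree under canonical-multiset
  equality, which is why it is the comparator used everywhere.
* The swap operation validates maximality eagerly; it is undefined on
  non-maximal intervals and silently accepting one would break the
  solution-preservation guarantee. When the mirrored interval coincides
  with the interval itself, the exchange is applied once.
* One published table of a worked example contains a single cell
  inconsistent with the rotational pairing constraint; fixtures assert the
  recomputed value and the acceptance check excludes that cell.

## Limitations

Binary alphabets only; constant weight only (mixed-weight multisets are
rejected at construction); error-free compositions only. The enumerator's
exponential worst case is inherent to the problem — the package makes the
search deterministic and guarded, not polynomial. File formats are the
package's own plain-text dialects; these strings are abstract codewords, so
no FASTA/FASTQ ingestion is provided.
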