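# psrecon

Reconstruction of multisets of constant-weight binary strings from
prefix–suffix compositions.

## The problem

Readout in polymer- and DNA-based data storage often proceeds by breaking or
sequencing molecules from their ends, so that what is observed for each
codeword is not the string itself but the *composition* — the ordered pair
(number of zeros, number of ones) — of every prefix and every suffix, with no
labels saying which affix came from which molecule or which end. For a
multiset `H` of `h` binary strings of common length `n` and common weight
`w̄`, the observable is the multiset

    M(H) = ⋃_{t ∈ H} { composition of t[1..j], composition of t[n-j+1..n] : j = 1..n },

2nh compositions in total. `psrecon` answers the three questions a decoder
cares about:

* **One answer, fast.** `reconstruct_one()` builds a compatible multiset in
  O(nh) by a greedy assignment over the running-weight grid.
* **All answers.** `reconstruct_all()` enumerates every multiset compatible
  with `M`, up to reversal of individual strings (reversal is information
  the channel destroys), via a scan over "half strings" followed by an
  assembly of complementary halves.
* **Is the answer unique?** `is_unique()` decides unique reconstructibility
  up to reversal by a criterion on any single solution: between a
  component function and its partner at most two maximal intervals of
  disagreement may occur, and between any other two component functions at
  most one.

The workhorse abstraction is the *cumulative weight function* (CWF)
`f(l, m)`: for each string `j`, odd label `m = 2j − 1` tracks the weight of
its length-`l` prefixes and even label `m = 2j` of its suffixes, subject to
`f(0, m) = 0`, unit steps, and the rotational pairing
`f(l, 2j−1) + f(n−l, 2j) = w̄`. A CWF *solves* `M` when its component
functions pass through each grid cell `(l, w)` exactly `a_{l,w}` times, where
`a_{l,w}` is the multiplicity of the composition `(l − w, w)` in `M`. The
grid decomposes into keep/drop flows `a = b + c` which drive both the greedy
solver and the complete enumerator; a brute-force oracle
(`oracle_reconstruct_all()`) provides independent ground truth on small
instances.

## Worked example

Three strings of length 6 and weight 4, two of them identical:

```r
library(psrecon)

u <- c("110101", "110101", "101110")
M <- composition_multiset(u)
M
#> Prefix-suffix composition multiset: n = 6, h = 3, w_bar = 4
#> 36 compositions over 10 non-zero grid cells

composition_count(M, zeros = 1, ones = 2)   # 6 affixes read as (1, 2)
#> [1] 6

reconstruct_one(M)
#> One multiset compatible with M (n = 6, h = 3, w_bar = 4):
#>   110110
#>   110101
#>   101101

reconstruct_all(M)
#> 3 compatible multiset class(es) (n = 6, h = 3, w_bar = 4):
#>   [1] {011011, 101011, 101101}
#>   [2] {011101, 101011, 101011}
#>   [3] {011101, 101101, 110011}

is_unique(M)$unique
#> [1] FALSE
```

The greedy answer is a perfectly valid decoding — its compositions equal
`M` — but it is not the transmitted multiset: three reversal classes are
compatible with these observations (the transmitted `u` canonicalizes to
class `[2]`), so this codebook cannot be decoded unambiguously. Compare a
four-string instance that can:

```r
v <- c("1000111", "1110001", "1100011", "1010011")
glance(reconstruct_all(composition_multiset(v)))
#> # A tibble: 1 × 6
#>       n     h w_bar n_classes n_scan_leaves unique
#>   <int> <int> <int>     <int>         <int> <lgl>
#> 1     7     4     4         1             1 TRUE
```

Results carry broom-style `tidy()`/`glance()` methods and `autoplot()`
renders the composition grid (with branching/merging points) and the CWF
component functions. Small plain-text examples live in `inst/extdata/`, and
`inst/cli/psrecon` exposes the same pipeline as a command line
(`compose`, `reconstruct`, `unique`, `oracle`, `simulate`).

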