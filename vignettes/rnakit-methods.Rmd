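---
title: "Methods: simplified-energy-model RNA structure and interaction prediction"
author: "rnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simplified-energy-model RNA structure and interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnakit)
```

## The structure model

An RNA of length $n$ is a string $S \in \{A,C,G,U\}^n$ with 1-based
positions.  A secondary structure is a set $P$ of ordered base pairs
$(i,j)$, $i<j$, subject to four constraints:

* each position occurs in at most one pair;
* pairs are complementary — by default Watson–Crick plus the G–U wobble,
  $\{A{-}U\},\{C{-}G\},\{G{-}U\}$ (`pair_rule("wc-gu")`); `"wc"` drops the
  wobble and `"any"` admits every letter combination;
* no two pairs cross ($\nexists\, i<p<j<q$): structures are *nested*, which
  is what makes interval dynamic programming possible;
* a minimal loop length $l$: $(i,j)$ is admissible only if $j-i>l$, i.e. a
  pair encloses at least $l$ positions.  Default $l = 3$, the conventional
  steric minimum for a hairpin loop.

The energy model deliberately ignores all structural context: every pair
contributes the same energy $E_{bp}$, so $E(P) = |P|\cdot E_{bp}$.  Default
$E_{bp}=-1$ and $RT=1$, both dimensionless and configurable
(`energy_model()`); the model fixes no unit system, so we expose $RT$ as a
single temperature-like knob rather than resolving units.  The Boltzmann
weight of a pair is $q^{bp} = \exp(-E_{bp}/RT)$.  This strips away the
Nearest-Neighbor loop decomposition used by production tools (RNAfold,
UNAFold) while preserving every algorithmic idea; none of the numbers this
package produces are predictions about real molecules.

All recursions decompose an interval $[i,j]$ by the pairing state of its
*last* position $j$.  The enumeration oracle
(`enumerate_structures()`) instead branches on the *first* position of each
interval, giving an independently derived ground truth against which every
dynamic program is tested exactly (counts, optima) or to $10^{-9}$
(probabilities).

## Counting and the growth factor

`count_matrix()` fills $C_{i,j} = C_{i,j-1} + \sum_{i\le k<j-l,\ S_k S_j
\text{ compl.}} C_{i,k-1}\cdot C_{k+1,j-1}$ with $C$ over empty intervals
$=1$.  The empty-interval convention is what makes the product well defined
at $k=i$ and $k=j-1$.  Counts are kept as exact big integers (a small C++
base-$2^{32}$ integer under `src/`), because pairable sequences overflow
64-bit arithmetic near $n\approx 60$ and the growth utility needs exact
values at $n=501$.

`growth_factor(n, l)` specializes the recursion to length only (all pairs
admissible), $f(m) = f(m-1) + \sum_{k=1}^{m-l-1} f(k-1)f(m-k-1)$,
$f(0)=\dots=f(l+1)=1$, and reports $f(n+1)/f(n)$.  The 1-D recursion is
$O(n^2)$ big-integer work instead of $O(n^3)$ for the full matrix, so
$n=500$ runs in well under a second.  With $l=3$ the ratio rounds to 2.3 at
$n=500$; the $l$-unconstrained limit is about 2.62.

## Base-pair maximization and suboptimal enumeration

`nussinov_matrix()` replaces the count's sum/product with max/sum (+1 per
pair).  Two variants are kept on purpose: the unique last-position
decomposition, and an ambiguous four-case variant ($i$ unpaired, $j$
unpaired, pair $(i,j)$, bipartition).  Both compute identical optima, but
only the unique variant assigns each structure exactly one derivation —
which is why counting and partition functions require it, and why
suboptimal enumeration under the ambiguous variant emits duplicates.  The
package reports those duplicates rather than collapsing them: exposing the
ambiguity is the point.

Suboptimal enumeration (`enumerate_suboptimal()`, shared with MEA) follows
Wuchty's scheme: a work stack of partial tracebacks (list of unresolved
intervals, partial structure, score so far), expanding a state only while
its optimistic potential stays within `delta` of the optimum.  A work stack
rather than call-stack recursion keeps the depth bounded and the
enumeration resumable.  `delta` is an absolute score range (pairs, or
accuracy units for MEA); with `delta` spanning the whole score range the
unique variant reproduces the full ensemble exactly once, a completeness
property the tests assert against both the counting matrix and the oracle.
Traceback tie-breaking is deterministic: cases are evaluated in recursion
order (unpaired first), smallest pairing partner $k$ first.  Real-valued
(MEA) case checks use an absolute tolerance of $10^{-9}$.

## Partition function and probabilities

With weights multiplicative over pairs, the counting recursion becomes
McCaskill's partition function: `partition_matrices()` fills the
$Q$/$Q^{bp}$ split ($Q^{bp}_{i,j} = Q_{i+1,j-1}q^{bp}$ for admissible
pairs) and cross-checks it against the direct one-matrix recursion to
$10^{-12}$ relative at every fill.  Arithmetic is plain double precision
guarded by a sequence-length limit (default 150, configurable): at teaching
scale log-space or scaling tricks would only obscure the recursions, and
overflow is detected rather than silently rescaled.

Base-pair probabilities use the outside recursion: an external term plus a
term per directly enclosing admissible pair $(p,q)$, evaluated in strictly
decreasing span order so enclosing probabilities are final when consumed;
the division by $Q^{bp}_{p,q}$ only ever happens for admissible pairs
($Q^{bp}>0$).  The implementation keeps the quartic form of the recursion
(vectorized over the enclosing pair) — the cubic outer-partition-function
refinement is a deliberate non-goal.  Unpaired-region probabilities
$Pr^{ss}(i,j)$ reuse the same scheme with $Q^{bp}_{i,j}$ replaced by 1, the
weight of the enforced single-stranded region.  The region definition is
taken literally: no pair *end* may fall inside $[i,j]$, while pairs
spanning the region from outside remain allowed.  Position-wise unpaired
probabilities come from the pair probabilities,
$Pr^u(k) = 1-\sum_{i<k}Pr^{bp}(i,k)-\sum_{k<j}Pr^{bp}(k,j)$, and equal
$Pr^{ss}(k,k)$ — an identity the tests verify across the whole suite.

Dot-plot export applies a display floor of $10^{-6}$ ("invisibly small"
has no canonical cutoff; this one is configurable).

## Maximum expected accuracy

The expected accuracy of a structure,
$acc(P) = \sum_{(i,j)\in P} 2\gamma\,Pr^{bp}(i,j) + \sum_{k \text{ unpaired}}
Pr^u(k)$, maps ensemble features onto single structures; the factor 2
counts the two positions a pair covers and $\gamma$ (default 1, the neutral
choice since no canonical default exists) trades pairs against unpaired
positions.  The summation scoping follows the standard reading: the pair
term runs over the structure's pairs, the $Pr^u$ term over its unpaired
positions.  `mea_matrix()` maximizes $acc$ with the same unique
decomposition ($+Pr^u(j)$ for an unpaired $j$, $+2\gamma Pr^{bp}(k,j)$ for
a pair), and the shared enumerator yields optimal and suboptimal MEA
structures with `delta` as an absolute accuracy range (a relative range
would behave erratically near $acc \approx 0$).  At $\gamma=0$ the open
chain is always optimal; at large $\gamma$ the MEA structure approaches the
pair-maximal one, and its pair count is non-decreasing in $\gamma$ on the
test grid.

## RNA–RNA interaction prediction

Molecules bind antiparallel, so the second sequence is handled through its
reversed view $S^{\leftarrow 2}_j = S^2_{m-j+1}$; every reported coordinate
is mapped back to the original 5'→3' numbering of both molecules.

**Hybridization-only** (`hybrid_only()`): a global-alignment-style prefix
recursion over intermolecular pairs only (match = pair, no gap cost).  All
distinct optimal pair sets are recovered by a memoized, per-cell
deduplicated traceback.  It is implemented directly from the prefix
recursion; the equivalence of its optimum with the best site-based duplex
energy (below, with unbounded gaps) is asserted as a cross-check on the
seeded pair suite.

**Concatenation / cofold** (`cofold()`): the two sequences are joined by a
linker of `X` characters of length $l+1$ — long enough that the two
sequence ends may legally pair across it — and folded with the unique
recursion, `X` excluded from pairing; linker-containing loops need no
special energy treatment in this model.  Output uses `()` for
intramolecular pairs, `[]` for linker-spanning (intermolecular) pairs, `X`
for the linker.

**Accessibility-based** (`interaction_predict()`): a two-step model —
molecules fold first, then interact — scored as
$I = D + \Delta E^1_{i..k} + \Delta E^2_{j..l}$.  The duplex table $D$ is
filled by an initiation/extension recursion over admissible boundary pairs,
with the distance between consecutive intermolecular pairs bounded by
`max_gap` on both molecules symmetrically (default 15, within the "small
constant" regime; `Inf` available for tiny inputs).  $D$ is stored over the
admissible-boundary-pair index set rather than a dense 4-D array.  Opening
penalties are $\Delta E_{i..j} = -RT\log Pr^{ss}(i,j) \ge 0$, computed per
molecule in isolation, for the second molecule on its reversed view.
Interactions with $I<0$ are favorable; all co-optimal interactions are
reported (ordered by site starts), and a flag exposes all favorable ones
instead.

On the worked duplex CCC / CCCGGGGGG the three paradigms disagree exactly
as intended: hybridization-only pairs the Cs with any three Gs
(`choose(6,3)` co-optimal sets); cofold buries the central Gs in an
intramolecular hairpin so the reported optimum's intermolecular pairs sit
on the 3'-terminal Gs (positions 7–9 — though the strict co-optimal set
also contains variants touching position 6); the accessibility optimum
interacts with the hairpin *loop* (central region, positions 4–6), a
kissing-stem-loop pattern cofold cannot represent.

## Fixtures and what the tests do (and do not) show

`generate_fixtures()` produces the seeded random suites used throughout the
tests: 50 sequences of length 5–12 with uniform base composition for the
single-molecule oracle suite, and 30 partner pairs of length 4–10 for the
interaction suite.  Lengths are capped by the exhaustive oracle's
exponential cost, not by the dynamic programs (the DP guard sits at
$n=150$).  The generator emulates composition and length only — no
conserved structure, no real transcript families — so passing tests
demonstrate algorithmic correctness of the recursions against enumeration,
not predictive accuracy on biological RNAs (which the simplified energy
model does not attempt).

One intuitive ordering does *not* survive testing: the hybridization-only
optimum bounds the other paradigms' intermolecular pair counts, but a
favorable accessibility interaction can carry more intermolecular pairs
than any cofold co-optimum — e.g. when every cofold optimum is purely
intramolecular while a kissing-type interaction is still favorable.  The
tests therefore assert only the two universally valid bounds.

## Numerical choices, degenerate inputs, limitations

* Empty sequences are legal where meaningful (count 1, $Z=1$); duplexes
  require both molecules non-empty.
* Guards raise typed conditions (`rnakit_guard_error`), mapped to exit
  code 3 by the CLI; malformed input maps to exit code 2.
* $Pr^{ss}$ is clamped to $[0,1]$ before the log so floating-point noise
  cannot produce negative penalties; $Pr^{ss}=0$ is impossible (the empty
  structure always contributes weight 1) and treated as an internal fault.
* Exact integers only where exactness matters (counting); probabilities and
  energies are doubles.
* Text output prints 6 decimals; JSON keeps full precision and embeds the
  serialized run configuration for reproducibility.
* Not covered, by design: pseudoknots, Nearest-Neighbor energies, Zuker
  minimum-free-energy folding, stochastic sampling, concentration terms,
  the cubic outside-recursion speedup, and heuristic accessibility
  approximations used by genome-scale tools.
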