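---
title: "Shape-aware mutation design: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-aware mutation design: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapedesign)
```

# The design problem

Given a wild-type DNA sequence of length $n$ and a set of at most seven
mutable positions, `shapedesign` enumerates the full Cartesian product of
$\{A,C,G,T\}$ at those positions — $4^m$ candidates for $m$ positions,
including the unmutated wild type, capped at $4^7 = 16384$ — and places
every candidate in the two-dimensional plane of *base distance* (how much
the protein-facing edge chemistry changed) versus *shape distance* (how
much the predicted helix geometry changed). The user then selects
candidates from the ranked panel or from its Pareto front.

# Base readout: the physicochemical encoding

A Watson–Crick base pair presents four functional groups on its
major-groove edge and three on its minor-groove edge, each one of
ACCEPTOR, DONOR, NONPOLAR_H or METHYL. Reading the groups in a fixed
spatial order 5'→3' along the reference strand:

| pair (from) | major-groove edge | minor-groove edge |
|---|---|---|
| A:T (A side) | ACCEPTOR, DONOR, ACCEPTOR, METHYL | ACCEPTOR, NONPOLAR_H, ACCEPTOR |
| G:C (G side) | ACCEPTOR, ACCEPTOR, DONOR, NONPOLAR_H | ACCEPTOR, DONOR, ACCEPTOR |

T and C use the reversed lists of their complements, because viewing the
same pair from the other strand reverses the spatial order of its groups.
Two structural facts fall out of the table: the encoding of a base's
complement is the group-order reversal of its own (so all derived distances
are strand-flip invariant), and A/T share a minor-groove list, as do G/C —
the minor-groove edge cannot resolve base-pair orientation.

Each group becomes a length-4 one-hot; concatenation gives a 16-slot major
vector, a 12-slot minor vector, 28 slots total with exactly 7 set. The
**physicochemical base distance** is the position-wise L1 difference of
these vectors, summed along the sequence. "Position-wise difference" is
deliberately taken as L1 on the binary vectors: it is the simplest choice
consistent with summation, and it makes the plain one-hot distance (2 per
mismatched position) a special case of the same construction. Under the
frozen table a substitution costs 6 when the pairs share most edge
chemistry (A↔C, G↔T) and 8 otherwise — so the physicochemical and one-hot
encodings, while equivalent as injective codes, induce *different*
metrics, and the package exposes both rather than forcing agreement.
Levenshtein distance (unit-cost edits, computed by dynamic programming via
`utils::adist`) is provided for unequal-length comparisons; it plays no
role in the equal-length design loop.

# Shape readout

## The feature catalogue

Fourteen features, named by the standard rigid-body nomenclature: six
base-pair step parameters (Shift, Slide, Rise, Tilt, Roll, HelT), six
intra-base-pair parameters (Shear, Stretch, Stagger, Buckle, ProT,
Opening) and two groove features (minor groove width MGW, minor-groove
electrostatic potential EP). For a length-$n$ sequence, step features have
$n-1$ values and all others $n$ values. Each feature carries a
reverse-complement parity: Shift, Tilt, Shear and Buckle change sign when
the molecule is read on the opposite strand (their sign conventions are
handed); the rest, including both groove features, are preserved. EP is
stored as given by the table, more negative meaning more negative
potential (the narrow-minor-groove signature); no rescaling is applied.

## The k-mer lookup predictor

The predictor contract is minimal — given a sequence, return one vector
per feature obeying the length contract — and the reference backend is a
complete k-mer lookup table: one value per feature for each of the $4^k$
words (k odd; default $k=5$, the classical pentamer scale for local shape
models). Three coordinate conventions pin the computation down:

* **Positions.** An intra-base-pair or groove value at position $i$ is the
  table value of the width-$k$ window centred on $i$.
* **Steps.** Step $t$ lies between positions $t$ and $t+1$. For odd $k$ no
  single step of a k-mer is its own image under reverse complement, so a
  "central step of one window" convention cannot be strand-consistent.
  Instead the step value is the *average of the table values of the two
  windows centred on the step's flanking positions* $t$ and $t+1$. With a
  parity-consistent table this symmetrised convention makes profiles
  exactly reverse-complement equivariant — symmetric features reverse,
  antisymmetric features reverse and negate — at every position, which is
  the property the tests assert. The price is a slightly wider footprint:
  a step depends on positions $t-h \ldots t+h+1$ where $h=(k-1)/2$.
* **Edges.** Within $h$ positions of either end the window extends past
  the molecule. The default `"mean"` policy marginalises the table over
  the missing flank bases (the mean over all k-mers matching the
  in-sequence context), preserving the $n$ / $n-1$ length contract; it
  commutes with reverse complement because reverse complement is a
  bijection on each matching set. `"nan"` and `"trim"` are available when
  edge values should be flagged or dropped instead. The edge policy is an
  explicit convention of this backend, not a claim about how any
  particular trained shape model treats sequence ends.

A point substitution therefore perturbs intra/groove values only within
$h$ positions of the edit and step values only within the adjacent steps —
the locality that makes focal design meaningful.

## The synthetic table generator

`synth_table(k, features, seed)` draws one Gaussian deviate $g(w)$ per
k-mer and feature and symmetrises it,
$v(w) = \big(g(w) + \pi_f\, g(\mathrm{revcomp}(w))\big)/2$ with
$\pi_f = \pm 1$ the feature's parity, then places the result on each
feature's conventional scale (e.g. MGW centred at 5.1 Å with spread
0.45 Å, HelT at 34.3° ± 1.5°, antisymmetric features centred at 0 by
necessity). The scales were chosen once, as typical magnitudes a
structural biologist would recognise, so that multi-feature normalization
is exercised on genuinely incommensurate units. Identical inputs give
byte-identical tables, and the caller's RNG stream is left untouched.

What the generator emulates: a complete, parity-consistent, local
sequence→shape map on realistic scales. What it does not: actual shape
biophysics — values at neighbouring k-mers are independent, whereas real
shape tables are smooth in sequence space. Passing tests therefore
demonstrate the correctness of the *machinery* (coordinates, parities,
lengths, distances, ranking, I/O) on any conforming backend, not the
biological plausibility of any designed oligo; for real design work a
published table should be supplied in the documented text format.

# Distances, focal regions, ranking

**Focal restriction.** Focal positions (default: all) restrict the shape
distance to a region of interest, e.g. the spacer between cooperative
binding sites. Position-indexed features use the focal positions directly;
step features use every step with *at least one endpoint* in the focal set
— a focal nucleotide participates in both adjacent steps, and excluding
half-overlapping steps would hide shape change at the focal base itself.

**Euclidean distance** is the square root of the sum of squared
differences pooled over the selected features and focal indices. When two
or more features are combined their units are incommensurate (Å versus
degrees), so by default values are first z-scored per feature, with mean
and SD pooled over the *entire candidate ensemble* — ensemble pooling
keeps the comparison consistent across candidates within a run, at the
cost of making the normalized distance run-dependent. For a single feature
normalization defaults to off. Both behaviours sit behind the `normalize`
flag and the choice is echoed in the output header; when the metric is
called standalone with normalization on and no ensemble statistics, the
statistics are pooled over the two profiles being compared.

**Pearson distance** is $1 - r$ per feature over the focal indices,
averaged over features, range $[0, 2]$. It is invariant to per-feature
offset and scale — it preserves the *pattern* of a shape parameter along
the sequence rather than its absolute values — so normalization is
irrelevant to it. Degenerate inputs are hard errors, not silent zeros: a
constant restricted profile has no defined correlation, and fewer than
three usable focal values per feature is refused.

**Ranking and ties.** Candidates are sorted by shape distance in the
objective direction (maximize by default), ties broken by ascending base
distance, then lexicographic sequence — a total order, so identical runs
produce identical output, which the I/O layer turns into byte-identical
files (fixed 6-decimal formatting, binary-mode writes, no timestamps).

**Pareto front.** Base distance is always minimized; shape distance
follows the objective. A candidate is dominated when another is at least
as good in both coordinates and strictly better in one; exact ties with a
front point are kept. The wild type is excluded when maximizing (its zero
shape change is the anti-goal) and is flagged, not dropped, everywhere
else — the $4^m$ panel deliberately includes it as the baseline row.

# Interfaces

Sequences enter as bare strings or single-record FASTA (multi-record files
are an error, not a silent first-record pick). The k-mer table format is
tab-separated text with a `kmer` + feature-name header, `#` comments,
order-irrelevant rows; the reader validates structure (line-numbered
errors for ragged rows, non-numeric values, duplicates, mixed k),
completeness ($4^k$ rows per feature) and parity (warning by default,
promotable to an error). Results are written as provenance-headed TSV or
as JSON with `config` and `candidates` keys. The CLI is a thin wrapper
over `cli_main()`; flags may be preloaded from a flat `key = value` config
file (`--config`), with explicit flags taking precedence; exit status 2
marks usage errors, each with a single actionable message naming the
offending flag, and unknown feature names are answered with the nearest
valid name. All coordinates are 1-based
inclusive everywhere a user sees them, converted exactly once at the
boundary.

# Verification scales

The test suite favours exhaustive checks where the space is small and
seeded sampling where it is not: metric axioms and strand invariance of
the base metrics are exhaustive over all length-3 sequence pairs (with
length-2 coverage in the unit tests); the Levenshtein implementation is
checked against an independent recursive edit-path oracle exhaustively on
all pairs of sequences of length ≤ 2 and on several hundred seeded random
pairs at lengths 3–5; the profile length contract runs 100 random
sequences with $n$ between 5 and 50; design-run strand invariance runs 20
seeded (sequence, table) instances. These sizes are the package's chosen
verification scale: large enough to exercise every code path and boundary,
small enough that the whole suite runs in seconds.

# Limitations

* Only the four canonical bases: no 5-methylcytosine or other modified
  bases, no non-Watson–Crick pairing, no RNA. The explicit functional-group
  representation is the natural extension point for modified bases, but
  none is implemented.
* Substitutions only. Insertions and deletions are not design moves —
  profile comparison requires equal lengths — even though the Levenshtein
  metric itself handles unequal lengths.
* The predictor is local by construction (width-k context) and describes
  unbound DNA; protein-induced deformation and non-local structure are out
  of reach of any lookup backend.
* Shape values are only as good as the supplied table; the bundled
  generator is for testing and demonstration, not biology.
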