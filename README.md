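# shapedesign

Shape-aware design of DNA point mutations.

Transcription factors recognise their binding sites through two biophysical
readout modes. **Base readout** is the direct sensing of the chemical groups
a base pair presents on its groove edges — hydrogen-bond acceptors and
donors, nonpolar hydrogens and the thymine methyl. **Shape readout** is the
recognition of the sequence-dependent 3D geometry of the double helix, the
classic example being minor-groove narrowing and the enhanced negative
electrostatic potential it creates. A point mutation moves a sequence along
*both* axes at once, and the two are not interchangeable: a substitution
that barely changes the edge chemistry can reshape the groove, and vice
versa.

`shapedesign` is for experimentalists designing oligos — optimising a
binding site, perturbing shape while holding the edit count down, or probing
the spacer between cooperative sites. It enumerates **all** substitution
candidates of a wild-type sequence at up to seven chosen positions (the full
4^k Cartesian product, 16384 candidates at the cap) and scores every
candidate against the wild type:

* **base distance** `d_base(s, s') = Σ_i ‖E(s_i) − E(s'_i)‖₁`, where `E`
  maps a base pair to its 28-slot functional-group vector: four groups on
  the major-groove edge and three on the minor-groove edge, each a length-4
  one-hot, concatenated into a 16-slot major and 12-slot minor vector.
  Substitutions that preserve edge chemistry cost less (A↔C and G↔T cost 6,
  all others 8). One-hot encoding (2 per mismatch) and Levenshtein edit
  distance are available as alternatives.
* **shape distance**, over any subset of a 14-feature catalogue — six
  base-pair step parameters (Shift, Slide, Rise, Tilt, Roll, HelT; n−1
  values for a length-n sequence), six intra-base-pair parameters (Shear,
  Stretch, Stagger, Buckle, ProT, Opening; n values) and two groove features
  (MGW, EP; n values). Either Euclidean distance on the profiles
  (optionally z-scored per feature across the candidate ensemble) or the
  Pearson pattern distance `mean_f (1 − r_f) ∈ [0, 2]`, which ignores a
  profile's absolute level and compares only its pattern. Distances can be
  restricted to **focal positions** — the region whose shape you actually
  care about.

Shape profiles come from a pluggable predictor backend: a k-mer lookup
table (default k = 5) in a documented plain-text format, reverse-complement
parity-checked on load. A deterministic synthetic-table generator
(`synth_table()`) provides structurally valid backends for testing and
demos; published pentamer shape tables in the same format plug straight in.

## Worked example

Scan two positions of a 20-mer, score MGW and Roll changes inside a focal
window, and extract the Pareto front (most shape change for the least edge
chemistry change):

```r
library(shapedesign)

tab <- synth_table(5, c("MGW", "Roll"), seed = 42)
res <- run_design("ACGTTGCAGGTACGATCAGT", positions = c(9, 11),
                  cfg = distance_config(features = c("MGW", "Roll"),
                                        focal = 8:14),
                  table = tab)
head(res[, c("sequence", "substitutions", "base_distance",
             "shape_distance", "rank")], 5)
#>              sequence substitutions base_distance shape_distance rank
#>  ACGTTGCAGGGACGATCAGT        11:T>G             6       6.270909    1
#>  ACGTTGCATGGACGATCAGT  9:G>T;11:T>G            12       6.258355    2
#>  ACGTTGCACGAACGATCAGT  9:G>C;11:T>A            16       6.155384    3
#>  ACGTTGCACGGACGATCAGT  9:G>C;11:T>G            14       5.954886    4
#>  ACGTTGCAAGGACGATCAGT  9:G>A;11:T>G            14       5.788592    5

pareto_front(res)[, c("sequence", "substitutions",
                      "base_distance", "shape_distance")]
#>              sequence substitutions base_distance shape_distance
#>  ACGTTGCAGGGACGATCAGT        11:T>G             6       6.270909
```

All 16 candidates are ranked (the wild type appears flagged, with both
distances 0). Here the single substitution `11:T>G` already achieves the
largest focal shape change in the panel — it dominates every double mutant,
so the Pareto front collapses to that one candidate: `base_distance = 6` is
the minimal physicochemical cost of one substitution, and
`shape_distance = 6.27` is the z-scored Euclidean norm of the MGW + Roll
profile change inside positions 8–14. (Values are from the seeded synthetic
backend; with a real shape table the numbers, not the mechanics, change.)

The same run from a shell:

```sh
Rscript exec/shapedesign --seq ACGTTGCAGGTACGATCAGT --positions 9,11 \
    --features MGW,Roll --focal 8-14 --synthetic-seed 42 \
    --pareto max --out design.tsv
```

which writes a provenance-headed TSV (plus `design.pareto.tsv`), and is
byte-identical across repeated identical invocations. `--demo
maximize_shape_change|minimize_shape_change|focal_spacer` writes a complete
self-contained scenario bundle instead.

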