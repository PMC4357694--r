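---
title: "Designing degenerate-codon libraries with dcopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate-codon libraries with dcopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcopt)
```

## The design problem

A degenerate codon (DC) is a triple of non-empty nucleotide sets, written
with the 15 IUPAC letters: `NNK` is {ACGT}{ACGT}{GT}. Synthesized as one
oligo position it produces a mixture of plain codons — its *degeneracy* —
and, through the genetic code, a set of amino acids. There are
(2^4 − 1)^3 = 3375 degenerate codons; `allDegenerateCodons()` enumerates
them in lexicographic IUPAC order, which is also the deterministic
tie-breaking order used everywhere in this package.

The library designer supplies, for each randomized position *i*, the count
`C_i(a)` of each amino acid *a* among a set of input sequences (typically
protein design trajectories or a multiple-sequence alignment). Choosing
codon set `D_i` at position *i* incurs the integer error

E_i(D_i) = Σ_a [a ∉ p(D_i)] · C_i(a) + Σ_a [a ∈ p(D_i)] · pen_i(a),

where p(D_i) is the union of amino acids the set produces and `pen_i` are
optional integer penalties for producing unwanted symbols. The objective is
the sum of position errors; the constraint is on the DNA size of the
library, the product over positions of the summed degeneracies, which must
stay at or below the diversity limit *L* set by the screening method's
throughput. The model deliberately carries no residue-pair information —
that extension is known to make the optimization NP-complete — and it
offers no reward for *excluding* unobserved amino acids; a zero count is
simply never penalized by absence. Tightening the diversity limit is the
lever that squeezes unobserved amino acids out (see the worked comparison
in the README).

STOP is a first-class 21st symbol `*`: it can carry counts, penalties, or a
forbidden flag like any amino acid. The standard genetic code
(`standardGeneticCode()`, from Biostrings) is the default; any complete
64-codon mapping onto the 21 symbols may be injected, but no alternate
tables ship.

## The dynamic programs

Because the error is integral and additive, the problem inverts: compute,
for every total error level *e*, the smallest achievable library size, then
pick the smallest *e* whose size fits the limit. With `s_i[e']` the
smallest single-codon size achieving error `e'` at position *i*
(`buildPositionTable()`),

S[i, e] = min over 0 ≤ e' ≤ min(e, m_i) of S[i−1, e−e'] · s_i[e'],

with a traceback table recording the argmin. `optimizeSingle()` iterates
the error level in the outermost loop; in the default `"output-sensitive"`
mode it stops at the first feasible level, so the work scales with the
optimum's error rather than with the full error range. `"full-table"` mode
populates every level up to Σ m_i so the complete Pareto front of
(error, minimal size) is available; the front is pruned to non-dominated
points.

`optimizeMulti()` allows up to `Lp` codons per position. Using several
codons within one contiguous primer *stretch* requires ordering the
cartesian product of primers, so the state grows to S[i, j, k, e]: *j*
primers total, *k* primers covering position *i*'s stretch. At a
first-in-stretch position the previous stretch's count is minimized over
and the new stretch starts at k = j′; elsewhere only divisors j′ of *k* are
legal and j′ codons demand k − k/j′ additional primers. The limits are
1 ≤ L_p ≤ L_s ≤ L_T (codons per position, primers per stretch, primers
total), with L_T at least the number of stretches; `Ls` defaults to `LT`
when not supplied. The stretch partition is an input — jointly optimizing
primer boundaries would require the flanking DNA sequence and annealing
temperatures, and is out of scope, as is any melting-temperature-aware
primer design.

In full-table mode the multi-codon DP stops extending the error axis once a
feasible library has been found *and* the front has reached the smallest
achievable library size: beyond that point the front is constant, and the
four-index traceback would otherwise dominate memory on large problems.

## Per-position tables and coverage-class reduction

`buildPositionTable()` computes, for each cardinality j′ ≤ L_p and each
achievable error, the minimal summed degeneracy over sets of exactly j′
distinct codons, with one witness set. Naively this costs O(3375^Lp) per
position. Only a codon's *coverage signature* — the subset of
error-relevant symbols (positive count, positive penalty, or required) it
produces — affects a set's error, so enumeration is restricted to, per
signature, the `Lp` codons of smallest degeneracy (ties toward the
lexicographically smaller IUPAC string). Up to `Lp` per class are kept, not
one, because a valid set may contain several same-signature codons; such
entries are always dominated for optimization, but the tables store them,
and the invariance of the tables under `useReduction = TRUE/FALSE` is part
of the test suite. Required symbols are included in the signature even when
their count is zero — natively required residues often have count 0, and a
purely count-based signature would let reduction discard every codon that
covers them. On the bundled problems the exported one-per-class
`coverageClassRepresentatives()` sets range from 8 to about 400 codons per
position.

Required coverage is a property of the *union* of a codon set, not of each
member; with a single codon the two readings coincide. This union reading
is what makes multiple codons valuable: {C, W, Y} with STOP forbidden is
unreachable by any single codon but costs only 3 DNA sequences as
TGG + TRT.

## Numeric and determinism choices

* **Sizes are doubles.** Library sizes are products of integers ≤ 192 per
  position and are held as R doubles, exact below 2^53. Every feasibility
  comparison happens at sizes no larger than the diversity limit (≤ 10^9
  in the bundled problems). Intermediate minimal sizes at very low error
  can exceed 2^53, where a 1-ulp rounding could at worst affect which of
  two equal-sized witnesses is reported, never an optimal error.
* **Tie-breaking.** Smallest position error e′ wins in every argmin, then
  the smallest codon count j′ (multi DP), then the lexicographically
  smallest witness tuple. Runs are byte-reproducible; the CLI test asserts
  identical JSON across repeated runs.
* **The error range 0 ≤ e′** includes zero-error contributions (positions
  already fully covered by a cheap codon contribute 0, as the bundled
  solutions show).
* **Diversity limits** given in scientific notation (`"3.2e8"`) are floored
  to exact integers.
* **Degenerate inputs.** A position whose admissible codons cannot cover
  its required symbols at any cardinality ≤ L_p is reported as infeasible
  by label; an unreachable size limit reports "no feasible library".
  Symbols with positive counts may not be forbidden.

`evaluateLibrary()` recomputes errors and sizes for any fixed assignment
rather than trusting reported numbers. For the bundled interface problem's
expert manual design this recomputation gives a per-position error of 31 at
position 268 (codon VDR misses A, D, H, N, S and T, with counts
3 + 8 + 1 + 6 + 7 + 6) and a total of 124; some published descriptions of
this design quote 29 and 122 for these entries. The package reports the
recomputed values. Likewise the manual LOV2 design's position 493 set
produces 9 distinct amino acids by recomputation. The manual LOV2 library
is evaluated with the native codon included at each position (emulating
fragment-spiking of the wild-type gene during assembly) and with the
intended leucine codon CTG at position 520 in place of the mistakenly
ordered CAG.

## The fixture generator and what tests do (not) show

`generateFixture()` emulates the shape of design-trajectory count tables:
per position it draws a fixed number of distinct amino acids uniformly and
multinomial counts over a fixed total, under a caller-supplied seed (the
session RNG state is restored). Defaults — 4 symbols per position, total
100 — mirror the sparsity of real design counts at a reduced scale at
which exhaustive enumeration remains a tractable exact cross-check: the
oracle-parity suite runs 200 seeded fixtures of 2–3 positions with
candidate lists restricted to the lexicographically first 5–8
coverage-class representatives, applied identically to the DP and to the
exhaustive oracle. Real tables differ in ways the generator does not
emulate: counts are strongly non-uniform (one dominant residue is common),
symbol subsets are biochemically correlated across positions, and real
problems are larger. Correctness on fixtures plus exact reproduction of
the two bundled full-scale problems is the evidence the tests provide;
the fixtures alone say nothing about wall-clock behaviour at scale.

The brute-force oracles (`bruteForcePositionTable()`,
`bruteForceOptimize()`) evaluate sets by plain expansion and translation,
sharing none of the bitmask or DP machinery, and refuse enumerations beyond
an explicit budget.

## Known limitations

* Errors and penalties must be integers — the DP indexes tables by error.
* The stretch partition is fixed by the user; primer thermodynamics are not
  modeled, and no primer DNA sequences are emitted (flanking DNA is not an
  input).
* Scores defined over input *sequence sets* (how many input sequences a
  library reproduces exactly) are not computed; the package's objective is
  the per-position count coverage above.
* Spiked (non-uniform nucleotide ratio) codons are not modeled; a position's
  nucleotide sets are uniform mixtures.
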