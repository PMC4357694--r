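# dcopt — degenerate-codon library design by integer dynamic programming

Directed evolution screens can only test a limited number of DNA sequences —
roughly 10^3 in 96-well screening, 10^7 in yeast surface display, up to
10^13 in mRNA display. Degenerate codons (DCs) concentrate that budget on
the amino acids most likely to matter: one IUPAC codon such as `NNK` or
`NDT` encodes a whole mixture of plain codons at a randomized position. But
picking, by hand, the codon (or small set of codons) for each of a dozen
positions so that the library stays under its size limit while covering the
amino acids suggested by protein design simulations or alignments is slow
and error prone. `dcopt` does it exactly, in seconds, for anyone building
site-saturation or focused diversity libraries from per-position amino-acid
counts.

## The model

The input is a counts table: C_i(a) is the number of times amino acid *a*
was observed at position *i* among the input design sequences. The error of
assigning a degenerate codon *d* (or a set of codons, taken as the union of
their translations p(d)) to position *i* is

    E_i(d) = sum over a of [a not in p(d)] * C_i(a)  (+ optional integer
             penalties for producing unwanted symbols, e.g. STOP)

and the library's error is the sum over positions. The library size |D| is
the product over positions of the summed codon degeneracies. The package
minimizes total error subject to |D| <= L (the diversity limit), by dynamic
programming over integer error levels: S[i, e], the smallest library over
positions 1..i with error exactly e, satisfies

    S[i, e] = min over e' of S[i-1, e-e'] * s_i[e']

where s_i is the per-position table of smallest sizes by error. A traceback
table recovers the codons; scanning e upward, the first feasible error level
is the optimum, and the explored levels form the Pareto front of library
size against error. A second DP allows several codons per position while
budgeting primers: synthesizing a contiguous *stretch* with several codon
choices requires ordering the cartesian product of primers, so the state
additionally tracks primers used in total (<= L_T) and in the current
stretch (<= L_s), with at most L_p codons per position. Positions can also
carry required amino acids (the chosen codons' union must produce them) and
forbidden ones, and every symbol — including STOP, written `*` — can carry
counts or penalties.

All 3375 degenerate codons are considered at every position; for multi-codon
sets, enumeration runs over coverage-class representatives (codons grouped
by which error-relevant amino acids they produce), which shrinks the
candidate list to a few hundred without changing any optimum.

## Worked example

Design a two-codon-per-position library for the bundled protein-interface
problem (nine positions in two primer stretches, 200 input designs), with at
most 4 primers and at most 3.2 × 10^8 DNA sequences:

```r
library(dcopt)
problem <- exampleProblem("interface")
fit <- optimizeMulti(problem$positions, problem$layout, "3.2e8",
                     primerLimits(Lp = 2, LT = 4))
fit
#> LibraryOptimization (output-sensitive mode, diversity limit 3.2e+08)
#> LibrarySolution: 9 positions, total error 28, size 310,542,336
#>   268    VNK (error 0)
#>   269    DBG,RAK (error 4)
#>   270    DYA (error 5)
#>   271    KCA (error 6)
#>   272    DYG (error 1)
#>   276    KSA (error 0)
#>   330    RVK (error 9)
#>   331    VAK,WBG (error 3)
#>   332    VNK (error 0)
#>   primers per stretch: 2, 2 (total 4)
#>   Pareto front: 25 points (errors 0..28)
```

The optimum leaves out amino-acid observations of total weight 28 (out of
1800): the DP spends its two extra primers on positions 269 and 331, where a
single codon is most costly. The report mirrors the per-position statistics
of a library QC table:

```r
rep <- summarizeLibrary(fit, problem$positions)
rep$perPosition[, c("position", "codons", "nDNA", "nAA", "error")]
#>  position  codons nDNA nAA error
#>       268     VNK   24  16     0
#>       269 DBG,RAK   13  13     4
#>       ...
rep$totals$pctDesired   # 33.4 — % of library members with only desired AAs
rep$totals$aaDnaRatio   # 0.333
```

`paretoFront(fit)` lists, for every explored error level, the smallest
achievable library (e.g. zero error would need 1.0 × 10^10 sequences —
31× over budget). `evaluateLibrary()` scores any hand-built assignment the
same way, and `generateFixture()` produces seeded synthetic count tables.

A command-line wrapper is included:

```sh
Rscript inst/scripts/dcopt.R optimize --counts counts.tsv --limit 3.2e8 \
  --stretches "268,269,270,271,272,276|330,331,332" \
  --max-codons-per-position 2 --max-primers-total 4 \
  --out solution.json --report report.tsv --pareto pareto.tsv
```

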