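#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib dcopt, .registration = TRUE
NULL

#' The 21 amino-acid symbols
#'
#' One-letter codes for the 20 proteinogenic amino acids plus `"*"` for the
#' STOP signal, in the canonical order used throughout the package. STOP is a
#' first-class symbol: it can carry counts, penalties, or a forbidden flag
#' like any amino acid.
#'
#' @export
AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' A degenerate codon
#'
#' Three ordered nucleotide sets (IUPAC degeneracies), each a non-empty subset
#' of \{A, C, G, T\}. A degenerate codon describes the mixture of plain codons
#' synthesized at one randomized position of an oligo.
#'
#' @slot masks list of three character vectors, each a non-empty subset of
#'   `c("A","C","G","T")`, sorted.
#' @export
setClass("DegenerateCodon", representation(masks = "list"))

setValidity("DegenerateCodon", function(object) {
  m <- object@masks
  if (length(m) != 3L)
    return("a codon has exactly three nucleotide sets")
  for (i in seq_len(3L)) {
    mi <- m[[i]]
    if (length(mi) < 1L || length(mi) > 4L)
      return(sprintf("nucleotide set %d must contain 1-4 nucleotides", i))
    if (!all(mi %in% c("A", "C", "G", "T")))
      return(sprintf("nucleotide set %d contains a non-ACGT character", i))
    if (anyDuplicated(mi) || is.unsorted(mi))
      return(sprintf("nucleotide set %d must be sorted and duplicate-free", i))
  }
  TRUE
})

#' One randomized position of a library design problem
#'
#' Holds the observed amino-acid counts for the position (how often each
#' symbol appeared among the input design sequences), optional integer
#' penalties for symbols that are tolerated but unwanted, and sets of
#' required and forbidden symbols.
#'
#' @slot label position identifier (e.g. a residue number as a string).
#' @slot counts named integer-valued numeric over [AA_SYMBOLS].
#' @slot penalties named integer-valued numeric over [AA_SYMBOLS].
#' @slot required character, symbols the chosen codon set must cover.
#' @slot forbidden character, symbols no chosen codon may produce.
#' @export
setClass("PositionSpec", representation(
  label = "character", counts = "numeric", penalties = "numeric",
  required = "character", forbidden = "character"))

setValidity("PositionSpec", function(object) {
  if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
    return("label must be a single non-empty string")
  for (fld in c("counts", "penalties")) {
    v <- slot(object, fld)
    if (!identical(names(v), AA_SYMBOLS))
      return(sprintf("%s must be named by the 21 amino-acid symbols", fld))
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
      return(sprintf("%s must be non-negative integers", fld))
  }
  if (!all(object@required %in% AA_SYMBOLS))
    return("required contains an unknown symbol")
  if (!all(object@forbidden %in% AA_SYMBOLS))
    return("forbidden contains an unknown symbol")
  if (length(intersect(object@required, object@forbidden)))
    return("a symbol cannot be both required and forbidden")
  if (any(object@counts[object@forbidden] > 0))
    return("a symbol with a positive count may not be forbidden")
  TRUE
})

#' Per-position table of smallest library sizes
#'
#' For position `i` the table holds, for each codon-set cardinality `j'`
#' between 1 and `Lp` and each achievable integer error `e'`, the smallest
#' combined DNA size of a set of exactly `j'` distinct degenerate codons whose
#' translated union covers every required symbol, together with one witness
#' set. Rows absent from the table are infeasible (error, cardinality)
#' combinations. Consumed by both dynamic programs.
#'
#' @slot label position identifier.
#' @slot Lp maximum codons per position the table was built for.
#' @slot entries data.frame with columns `ncodons`, `error`, `size` and a
#'   list-column `witness` of IUPAC codon vectors.
#' @slot maxError largest finite error stored.
#' @export
setClass("PositionTable", representation(
  label = "character", Lp = "integer", entries = "data.frame",
  maxError = "integer"))

setValidity("PositionTable", function(object) {
  e <- object@entries
  need <- c("ncodons", "error", "size", "witness")
  if (!all(need %in% names(e)))
    return("entries must have columns ncodons, error, size, witness")
  if (nrow(e) && any(e$size < 1))
    return("stored sizes must be positive")
  TRUE
})

#' Partition of the designable positions into primer stretches
#'
#' An ordered list of stretches, each an ordered vector of position labels.
#' Positions within a stretch are contiguous in the global position order;
#' synthesizing a stretch with several codon choices requires purchasing the
#' cartesian product of primers.
#'
#' @slot stretches list of character vectors of position labels.
#' @export
setClass("StretchLayout", representation(stretches = "list"))

setValidity("StretchLayout", function(object) {
  s <- object@stretches
  if (!length(s)) return("at least one stretch required")
  if (!all(vapply(s, function(x) is.character(x) && length(x) >= 1L, TRUE)))
    return("each stretch must be a non-empty character vector of labels")
  lab <- unlist(s)
  if (anyDuplicated(lab)) return("a position may appear in only one stretch")
  TRUE
})

#' Primer budget limits
#'
#' @slot Lp maximum degenerate codons per position.
#' @slot Ls maximum primers per stretch (the product of codon counts over the
#'   stretch's positions).
#' @slot LT maximum primers total.
#' @export
setClass("PrimerLimits", representation(Lp = "integer", Ls = "integer",
                                        LT = "integer"))

setValidity("PrimerLimits", function(object) {
  v <- c(object@Lp, object@Ls, object@LT)
  if (any(is.na(v)) || any(v < 1L)) return("limits must be positive integers")
  if (!(object@Lp <= object@Ls && object@Ls <= object@LT))
    return("limits must satisfy Lp <= Ls <= LT")
  TRUE
})

#' A designed degenerate-codon library
#'
#' @slot labels position labels in design order.
#' @slot codonSets named list; per position, the chosen IUPAC codons (sorted).
#' @slot positionErrors numeric, per-position error contributions.
#' @slot totalError total error of the library.
#' @slot librarySize number of DNA sequences the library defines (product of
#'   per-position codon-set sizes).
#' @slot primerCounts per-stretch primer counts (products of codon counts);
#'   `NA` when no stretch layout applies.
#' @slot primerTotal total primers to purchase.
#' @export
setClass("LibrarySolution", representation(
  labels = "character", codonSets = "list", positionErrors = "numeric",
  totalError = "numeric", librarySize = "numeric", primerCounts = "numeric",
  primerTotal = "numeric"))

#' Result of a library optimization
#'
#' Bundles the minimal-error feasible library with the Pareto front of
#' (total error, minimal library size) points explored by the dynamic
#' program.
#'
#' @slot solution a [LibrarySolution-class].
#' @slot pareto data.frame with columns `error` and `size`: for each error
#'   level on the front, the smallest achievable library size (dominated
#'   points pruned; sizes strictly decreasing).
#' @slot diversityLimit the library-size limit used.
#' @slot mode `"output-sensitive"` or `"full-table"`.
#' @export
setClass("LibraryOptimization", representation(
  solution = "LibrarySolution", pareto = "data.frame",
  diversityLimit = "numeric", mode = "character"))
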