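# Evaluate a given codon assignment under the error model (e.g. a manually
# designed library), producing the same LibrarySolution object the optimizers
# return.

#' Evaluate a fixed codon assignment
#'
#' Scores an explicit per-position codon assignment -- for example a manually
#' designed library -- under the same error model the optimizers use: the
#' union-coverage error per position, the product library size, and (given a
#' layout) the primer counts.
#'
#' @param positions list of [PositionSpec-class] in design order.
#' @param codonSets list of IUPAC codon vectors, one per position (recycled
#'   names must match position labels if named).
#' @param layout optional [StretchLayout-class] for primer accounting.
#' @param code genetic code.
#' @return a [LibrarySolution-class].
#' @examples
#' specs <- list(positionSpec("1", c(C = 1, W = 1, Y = 1)))
#' evaluateLibrary(specs, list(c("TGG", "TRT")))  # error 0, size 3
#' @export
evaluateLibrary <- function(positions, codonSets, layout = NULL,
                            code = standardGeneticCode()) {
  labs <- .checkPositions(positions)
  stopifnot(length(codonSets) == length(positions))
  if (!is.null(names(codonSets)) && !identical(names(codonSets), labs))
    stop("codonSets names must match position labels, in order")
  sets <- lapply(codonSets, function(s) {
    s <- vapply(s, formatCodon, "")
    unname(s[order(s, method = "radix")])
  })
  .makeSolution(labs, sets, positions, layout, code)
}
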