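# Library summary statistics: per-position DNA/amino-acid counts, the
# percentage of desired codons and library members, totals and the AA:DNA
# ratio.

#' Summarize a designed library
#'
#' Per position: the codon set, its translated amino-acid union, the DNA count
#' (sum of degeneracies), the amino-acid count (union cardinality), and the
#' desired-codon percentage -- 100 times the fraction of expanded DNA codons,
#' counted with multiplicity across the codon set, whose translation has a
#' positive count at that position (STOP and unobserved symbols are
#' undesired). Totals: DNA size (product of DNA counts), amino-acid sequence
#' count (product of union cardinalities), the percentage of library members
#' containing only desired amino acids (product of per-position fractions),
#' total error, and the AA:DNA ratio. Values are exact; rounding to display
#' precision happens only in [writeReportTsv()].
#'
#' @param solu a [LibrarySolution-class] (or [LibraryOptimization-class]).
#' @param positions list of [PositionSpec-class] matching the solution.
#' @param code genetic code.
#' @return list with `perPosition` (data.frame) and `totals` (list).
#' @export
summarizeLibrary <- function(solu, positions, code = standardGeneticCode()) {
  if (is(solu, "LibraryOptimization")) solu <- solu@solution
  stopifnot(is(solu, "LibrarySolution"))
  labs <- .checkPositions(positions)
  stopifnot(identical(labs, solu@labels))
  per <- lapply(seq_along(positions), function(i) {
    spec <- positions[[i]]
    set <- solu@codonSets[[i]]
    plain <- unlist(lapply(set, expandCodon), use.names = FALSE)
    tr <- unname(code[plain])
    desired <- AA_SYMBOLS[spec@counts > 0]
    un <- aminoAcidSet(set, code = code)
    data.frame(
      position = spec@label,
      codons = paste(set, collapse = ","),
      aminoAcids = paste(un, collapse = ""),
      nDNA = length(plain),
      nAA = length(un),
      fracDesired = mean(tr %in% desired),
      error = codonSetError(spec, set, code = code))
  })
  per <- do.call(rbind, per)
  totals <- list(
    dnaSize = prod(per$nDNA),
    aaSize = prod(per$nAA),
    fracDesired = prod(per$fracDesired),
    pctDesired = 100 * prod(per$fracDesired),
    error = sum(per$error),
    aaDnaRatio = prod(per$nAA) / prod(per$nDNA))
  stopifnot(totals$dnaSize == solu@librarySize,
            totals$error == solu@totalError)
  list(perPosition = per, totals = totals)
}

.fmtSize <- function(x) {
  if (x >= 1e6) sprintf("%s (%.1e)", format(x, big.mark = "", scientific = FALSE), x)
  else format(x, scientific = FALSE)
}

#' Write a library report as TSV
#'
#' One row per statistic (codons, amino acids, #NA, #AA, %Des, error), one
#' column per position plus a totals column. Per-position percentages are
#' rounded to the nearest integer and the total to one decimal; sizes of a
#' million or more are also rendered in scientific notation.
#'
#' @param report result of [summarizeLibrary()].
#' @param path output file.
#' @export
writeReportTsv <- function(report, path) {
  p <- report$perPosition
  t <- report$totals
  rows <- rbind(
    c("DCs", p$codons, ""),
    c("AAs", p$aminoAcids, ""),
    c("#NAs", p$nDNA, .fmtSize(t$dnaSize)),
    c("#AAs", p$nAA, .fmtSize(t$aaSize)),
    c("%Des", round(100 * p$fracDesired), sprintf("%.1f", t$pctDesired)),
    c("Error", p$error, t$error))
  colnames(rows) <- c("stat", p$position, "Totals")
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Pareto front as TSV
#'
#' Columns: error, minimal library size, log10 size (for plotting).
#'
#' @param opt a [LibraryOptimization-class] (or a data.frame with columns
#'   `error` and `size`).
#' @param path output file.
#' @export
writeParetoTsv <- function(opt, path) {
  front <- if (is(opt, "LibraryOptimization")) opt@pareto else opt
  stopifnot(all(c("error", "size") %in% names(front)))
  out <- data.frame(error = front$error,
                    size = format(front$size, scientific = FALSE),
                    log10size = round(log10(front$size), 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
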