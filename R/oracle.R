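# Brute-force reference implementations used as test oracles. These work
# directly on expanded codons and plain set operations -- deliberately
# independent of the bitmask machinery and the dynamic programs they check --
# and are guarded by enumeration budgets. Never intended for full-size
# problems.

.oracleSetStats <- function(spec, codons, code) {
  covered <- aminoAcidSet(codons, code = code)
  err <- sum(spec@counts[setdiff(AA_SYMBOLS, covered)]) +
    sum(spec@penalties[covered])
  list(error = err, size = sum(vapply(codons, codonDegeneracy, 0)),
       covered = covered)
}

# all admissible codon subsets of size 1..Lp at a position (candidates given),
# as a data.frame of (ncodons, error, size) with a witness list-column
.oracleSubsets <- function(spec, Lp, candidates, code, budget) {
  keep <- vapply(candidates, function(cd)
    !length(intersect(aminoAcidSet(cd, code = code), spec@forbidden)), TRUE)
  candidates <- sort(candidates[keep])
  ncombos <- sum(vapply(seq_len(Lp), function(j) choose(length(candidates), j), 0))
  if (ncombos > budget)
    stop(sprintf("oracle budget exceeded (%.3g sets > %.3g)", ncombos, budget))
  out <- list()
  for (j in seq_len(min(Lp, length(candidates)))) {
    sets <- utils::combn(candidates, j, simplify = FALSE)
    for (st in sets) {
      stats <- .oracleSetStats(spec, st, code)
      if (!all(spec@required %in% stats$covered)) next
      out[[length(out) + 1L]] <- data.frame(ncodons = j, error = stats$error,
                                            size = stats$size,
                                            witness = I(list(st)))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Brute-force per-position table
#'
#' Exhaustive minimization over all unordered codon sets of size up to `Lp`
#' drawn from `candidates`, returning the same table [buildPositionTable()]
#' computes. Used as the independent oracle in tests.
#'
#' @param spec a [PositionSpec-class].
#' @param Lp maximum codons per set.
#' @param candidates character vector of candidate IUPAC codons.
#' @param code genetic code.
#' @param budget maximum number of sets to enumerate.
#' @return a [PositionTable-class].
#' @export
bruteForcePositionTable <- function(spec, Lp, candidates,
                                    code = standardGeneticCode(),
                                    budget = 2e6) {
  all <- .oracleSubsets(spec, Lp, candidates, code, budget)
  if (is.null(all))
    stop(sprintf("position infeasible: \"%s\"", spec@label))
  rows <- list()
  for (j in unique(all$ncodons)) {
    sub <- all[all$ncodons == j, , drop = FALSE]
    for (e in sort(unique(sub$error))) {
      se <- sub[sub$error == e, , drop = FALSE]
      b <- which(se$size == min(se$size))[1L]  # combn order is lexicographic
      rows[[length(rows) + 1L]] <- se[b, , drop = FALSE]
    }
  }
  entries <- do.call(rbind, rows)
  entries <- entries[order(entries$ncodons, entries$error), , drop = FALSE]
  rownames(entries) <- NULL
  entries$witness <- unclass(entries$witness)
  new("PositionTable", label = spec@label, Lp = as.integer(Lp),
      entries = entries, maxError = as.integer(max(entries$error)))
}

#' Brute-force library optimization
#'
#' Exact optimum by enumeration of every assignment of admissible codon sets
#' (one set of at most `Lp` codons per position) satisfying the diversity and
#' primer limits. Returns the minimal-error assignment, ties broken toward
#' smaller size. Used as the independent oracle for both dynamic programs.
#'
#' @param positions list of [PositionSpec-class].
#' @param diversityLimit library-size limit.
#' @param candidates list of per-position candidate codon vectors.
#' @param layout optional [StretchLayout-class]; when given, `limits` primer
#'   constraints are enforced.
#' @param limits optional [PrimerLimits-class]; defaults to one codon per
#'   position, unlimited primers.
#' @param code genetic code.
#' @param budget maximum number of assignments to enumerate.
#' @return list with `error`, `size`, `codonSets`.
#' @export
bruteForceOptimize <- function(positions, diversityLimit, candidates,
                               layout = NULL, limits = NULL,
                               code = standardGeneticCode(), budget = 2e6) {
  L <- parseDiversityLimit(diversityLimit)
  labs <- .checkPositions(positions)
  Lp <- if (is.null(limits)) 1L else limits@Lp
  perPos <- lapply(seq_along(positions), function(i) {
    s <- .oracleSubsets(positions[[i]], Lp, candidates[[i]], code, budget)
    if (is.null(s)) stop(sprintf("position infeasible: \"%s\"", labs[i]))
    s
  })
  total <- prod(vapply(perPos, nrow, 0))
  if (total > budget)
    stop(sprintf("oracle budget exceeded (%.3g assignments > %.3g)", total, budget))
  grid <- do.call(expand.grid, c(lapply(perPos, function(s) seq_len(nrow(s))),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  err <- Reduce(`+`, lapply(seq_along(perPos), function(i)
    perPos[[i]]$error[grid[[i]]]))
  size <- Reduce(`*`, lapply(seq_along(perPos), function(i)
    perPos[[i]]$size[grid[[i]]]))
  ok <- size <= L
  if (!is.null(layout)) {
    ncod <- lapply(seq_along(perPos), function(i)
      perPos[[i]]$ncodons[grid[[i]]])
    names(ncod) <- labs
    total <- 0
    for (st in layout@stretches) {
      per <- Reduce(`*`, ncod[st])
      ok <- ok & per <= limits@Ls
      total <- total + per
    }
    ok <- ok & total <= limits@LT
  }
  if (!any(ok)) stop("no feasible assignment")
  err[!ok] <- Inf
  size[!ok] <- Inf
  b <- which(err == min(err))
  b <- b[which.min(size[b])]
  list(error = err[b], size = size[b],
       codonSets = stats::setNames(lapply(seq_along(perPos), function(i)
         perPos[[i]]$witness[[grid[[i]][b]]]), labs))
}
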