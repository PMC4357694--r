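# Multi-codon dynamic program with primer accounting over stretches, under
# limits on codons per position (Lp), primers per stretch (Ls) and primers
# total (LT).

#' Construct a stretch layout
#'
#' @param stretches list of character vectors of position labels; stretches
#'   and the positions within them must follow the global design order.
#' @export
stretchLayout <- function(stretches) {
  new("StretchLayout", stretches = lapply(stretches, as.character))
}

#' Construct primer limits
#'
#' @param Lp maximum degenerate codons per position.
#' @param Ls maximum primers per stretch; defaults to `LT`.
#' @param LT maximum primers total.
#' @export
primerLimits <- function(Lp, LT, Ls = LT) {
  new("PrimerLimits", Lp = as.integer(Lp), Ls = as.integer(Ls),
      LT = as.integer(LT))
}

.checkLayout <- function(layout, labs) {
  stopifnot(is(layout, "StretchLayout"))
  flat <- unlist(layout@stretches)
  if (!identical(unname(flat), unname(labs)))
    stop("stretch layout must partition the positions contiguously, in order")
  invisible(layout)
}

#' Count the primers a solution requires
#'
#' Per stretch, the number of primers to purchase is the cartesian product of
#' the number of codons chosen at each of its positions; the total is the sum
#' over stretches.
#'
#' @param solu a [LibrarySolution-class].
#' @param layout a [StretchLayout-class] covering exactly the solution's
#'   positions.
#' @return list with `perStretch` (named by first label of each stretch) and
#'   `total`.
#' @export
countPrimers <- function(solu, layout) {
  stopifnot(is(solu, "LibrarySolution"))
  .checkLayout(layout, solu@labels)
  per <- vapply(layout@stretches, function(st)
    prod(lengths(solu@codonSets[st])), 0)
  names(per) <- vapply(layout@stretches, `[`, "", 1L)
  list(perStretch = per, total = sum(per))
}

setMethod("show", "StretchLayout", function(object) {
  cat(sprintf("StretchLayout: %d stretch%s (%s)\n", length(object@stretches),
              if (length(object@stretches) == 1L) "" else "es",
              paste(vapply(object@stretches, paste, "", collapse = ","),
                    collapse = " | ")))
})

setMethod("show", "PrimerLimits", function(object) {
  cat(sprintf("PrimerLimits: Lp = %d codons/position, Ls = %d primers/stretch, LT = %d total\n",
              object@Lp, object@Ls, object@LT))
})

#' Optimize a library allowing several degenerate codons per position
#'
#' Extends the single-codon dynamic program with primer accounting: the state
#' tracks, besides the running total error, the number of primers purchased
#' in total (`j`) and for the current stretch (`k`); choosing `j'` codons at a
#' position multiplies the stretch's primer product by `j'`. Returns the
#' minimal-error library whose DNA size is within the diversity limit, using
#' at most `Lp` codons per position, at most `Ls` primers per stretch and at
#' most `LT` primers total.
#'
#' @param positions list of [PositionSpec-class] in design order.
#' @param layout a [StretchLayout-class] partitioning the positions.
#' @param diversityLimit maximum number of DNA sequences.
#' @param limits a [PrimerLimits-class] (see [primerLimits()]).
#' @param mode `"output-sensitive"` (stop at the first feasible error level)
#'   or `"full-table"` (extend the front until it reaches the minimal
#'   achievable library size).
#' @param tables optional precomputed list of [PositionTable-class] built
#'   with `Lp >= limits@Lp`.
#' @param useReduction use coverage-class reduction when building tables.
#' @param candidates optional list of per-position candidate restrictions
#'   (for oracle-parity tests).
#' @param code genetic code.
#' @return a [LibraryOptimization-class].
#' @export
optimizeMulti <- function(positions, layout, diversityLimit, limits,
                          mode = c("output-sensitive", "full-table"),
                          tables = NULL, useReduction = TRUE,
                          candidates = NULL, code = standardGeneticCode()) {
  mode <- match.arg(mode)
  stopifnot(is(limits, "PrimerLimits"))
  L <- parseDiversityLimit(diversityLimit)
  labs <- .checkPositions(positions)
  .checkLayout(layout, labs)
  nStretch <- length(layout@stretches)
  if (limits@LT < nStretch)
    stop("total primer limit must cover at least one primer per stretch")
  n <- length(positions)
  if (is.null(tables))
    tables <- lapply(seq_len(n), function(i)
      buildPositionTable(positions[[i]], Lp = limits@Lp,
                         useReduction = useReduction,
                         candidates = if (is.null(candidates)) NULL else
                           candidates[[i]],
                         code = code))
  dense <- lapply(tables, function(pt) {
    d <- .ptDense(pt)
    if (nrow(d) < limits@Lp)
      d <- rbind(d, matrix(NA_real_, limits@Lp - nrow(d), ncol(d)))
    d[seq_len(limits@Lp), , drop = FALSE]
  })
  firstLab <- vapply(layout@stretches, `[`, "", 1L)
  first <- labs %in% firstLab
  eCap <- sum(vapply(tables, function(pt) pt@maxError, 0L))
  minPossible <- if (mode == "full-table")
    prod(vapply(tables, function(pt) min(pt@entries$size), 0)) else -1

  res <- cpp_dp_multi(dense, first, limits@Lp, limits@Ls, limits@LT,
                      L, mode == "output-sensitive", eCap, minPossible)
  if (!res$feasible)
    stop(sprintf(
      "no feasible library: no codon assignment satisfies size <= %s within the primer limits",
      format(L, scientific = TRUE)))

  sets <- lapply(seq_len(n), function(i)
    .ptWitness(tables[[i]], res$choices[i, 1L], res$choices[i, 2L]))
  sol <- .makeSolution(labs, sets, positions, layout, code)
  # the traceback's internal primer indices must agree with recomputation
  pc <- countPrimers(sol, layout)
  stopifnot(sol@totalError == res$optError,
            pc$total == res$optJ,
            pc$perStretch[nStretch] == res$optK,
            all(pc$perStretch <= limits@Ls),
            pc$total <= limits@LT,
            all(lengths(sets) <= limits@Lp),
            sol@librarySize <= L)
  new("LibraryOptimization", solution = sol,
      pareto = .paretoFromSizes(res$minSizeByE),
      diversityLimit = L, mode = mode)
}
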