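# Single-codon-per-position dynamic program: smallest library size per total
# error level, traceback, Pareto front, and selection of the minimal-error
# library within the diversity limit.

#' Parse a diversity limit
#'
#' Accepts a number or a string in scientific notation (e.g. `"3.2e8"`) and
#' returns the exact integer floor as a numeric.
#'
#' @param x number or string.
#' @export
parseDiversityLimit <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v < 1) stop("diversity limit must be a positive number")
  floor(v)
}

# prune a vector of minimal sizes by error level into a Pareto front:
# keep error levels whose size strictly improves on every smaller error
.paretoFromSizes <- function(sizes) {
  err <- seq_along(sizes) - 1L
  keep <- logical(length(sizes))
  best <- Inf
  for (k in seq_along(sizes)) {
    if (!is.na(sizes[k]) && sizes[k] < best) {
      keep[k] <- TRUE
      best <- sizes[k]
    }
  }
  data.frame(error = err[keep], size = sizes[keep])
}

.checkPositions <- function(positions) {
  stopifnot(length(positions) >= 1L,
            all(vapply(positions, is, TRUE, "PositionSpec")))
  labs <- vapply(positions, function(p) p@label, "")
  if (anyDuplicated(labs)) stop("duplicate position labels")
  labs
}

#' Optimize a library with one degenerate codon per position
#'
#' Solves for the smallest library achieving each total error level by the
#' recursion `S[i, e] = min over e' of S[i-1, e-e'] * s_i[e']`, where `s_i` is
#' the per-position smallest-size table, then returns the minimal-error
#' library whose size does not exceed the diversity limit, reconstructed via
#' the traceback table. In `"output-sensitive"` mode (default) error levels
#' are explored outermost and the run stops at the first feasible level; in
#' `"full-table"` mode all error levels are populated so the complete Pareto
#' front is available.
#'
#' @param positions list of [PositionSpec-class] in design order.
#' @param diversityLimit maximum number of DNA sequences (number or string,
#'   see [parseDiversityLimit()]).
#' @param mode `"output-sensitive"` or `"full-table"`.
#' @param layout optional [StretchLayout-class], used only to report primer
#'   counts (one primer per stretch for single-codon solutions).
#' @param tables optional list of precomputed [PositionTable-class] (must have
#'   been built with `Lp = 1`); built from `positions` when `NULL`.
#' @param code genetic code.
#' @return a [LibraryOptimization-class].
#' @export
optimizeSingle <- function(positions, diversityLimit,
                           mode = c("output-sensitive", "full-table"),
                           layout = NULL, tables = NULL,
                           code = standardGeneticCode()) {
  mode <- match.arg(mode)
  L <- parseDiversityLimit(diversityLimit)
  labs <- .checkPositions(positions)
  n <- length(positions)
  if (is.null(tables))
    tables <- lapply(positions, buildPositionTable, Lp = 1L, code = code)
  s <- lapply(tables, function(pt) .ptDense(pt)[1L, ])
  m <- vapply(s, length, 0L) - 1L
  eCap <- sum(m)

  S <- matrix(NA_real_, nrow = n, ncol = eCap + 1L)
  Tb <- matrix(NA_integer_, nrow = n, ncol = eCap + 1L)
  optError <- NA_integer_
  explored <- eCap
  for (e in 0:eCap) {
    S[1L, e + 1L] <- if (e <= m[1L]) s[[1L]][e + 1L] else NA_real_
    if (n > 1L) for (i in 2:n) {
      ee <- 0:min(e, m[i])
      vals <- S[i - 1L, e - ee + 1L] * s[[i]][ee + 1L]
      if (!all(is.na(vals))) {
        b <- which.min(vals)  # first minimum: smallest e' wins ties
        S[i, e + 1L] <- vals[b]
        Tb[i, e + 1L] <- ee[b]
      }
    }
    if (is.na(optError) && !is.na(S[n, e + 1L]) && S[n, e + 1L] <= L)
      optError <- e
    if (!is.na(optError) && mode == "output-sensitive") {
      explored <- e
      break
    }
  }
  if (is.na(optError))
    stop(sprintf("no feasible library: no codon assignment has size <= %s",
                 format(L, scientific = TRUE)))

  perErr <- integer(n)
  e <- optError
  if (n > 1L) for (i in n:2) {
    perErr[i] <- Tb[i, e + 1L]
    e <- e - perErr[i]
  }
  perErr[1L] <- e
  sets <- lapply(seq_len(n), function(i) .ptWitness(tables[[i]], 1L, perErr[i]))
  sol <- .makeSolution(labs, sets, positions, layout, code)
  stopifnot(sol@totalError == optError)
  new("LibraryOptimization", solution = sol,
      pareto = .paretoFromSizes(S[n, seq_len(explored + 1L)]),
      diversityLimit = L, mode = mode)
}

# assemble and self-check a LibrarySolution from per-position codon sets
.makeSolution <- function(labs, sets, positions, layout, code) {
  names(sets) <- labs
  perErr <- vapply(seq_along(sets), function(i)
    codonSetError(positions[[i]], sets[[i]], code = code), 0)
  sizes <- vapply(sets, codonSetSize, 0)
  if (!is.null(layout)) {
    stopifnot(is(layout, "StretchLayout"))
    pc <- vapply(layout@stretches, function(st)
      prod(lengths(sets[st])), 0)
    pt <- sum(pc)
  } else {
    pc <- NA_real_
    pt <- if (all(lengths(sets) == 1L)) NA_real_ else NA_real_
  }
  new("LibrarySolution", labels = labs, codonSets = sets,
      positionErrors = perErr, totalError = sum(perErr),
      librarySize = prod(sizes), primerCounts = pc, primerTotal = pt)
}

#' Accessors for designed libraries
#'
#' `codonSets()` returns the chosen codon sets (named list of IUPAC vectors);
#' `totalError()` and `librarySize()` the library's error and DNA size;
#' `solution()` extracts the [LibrarySolution-class] from an optimization
#' result and `paretoFront()` its (error, minimal size) front.
#'
#' @param object a [LibrarySolution-class] or [LibraryOptimization-class].
#' @name library-accessors
#' @aliases codonSets totalError librarySize solution paretoFront
NULL

#' @rdname library-accessors
#' @export
setGeneric("codonSets", function(object) standardGeneric("codonSets"))
setMethod("codonSets", "LibrarySolution", function(object) object@codonSets)
setMethod("codonSets", "LibraryOptimization",
          function(object) object@solution@codonSets)

#' @rdname library-accessors
#' @export
setGeneric("totalError", function(object) standardGeneric("totalError"))
setMethod("totalError", "LibrarySolution", function(object) object@totalError)
setMethod("totalError", "LibraryOptimization",
          function(object) object@solution@totalError)

#' @rdname library-accessors
#' @export
setGeneric("librarySize", function(object) standardGeneric("librarySize"))
setMethod("librarySize", "LibrarySolution", function(object) object@librarySize)
setMethod("librarySize", "LibraryOptimization",
          function(object) object@solution@librarySize)

#' @rdname library-accessors
#' @export
setGeneric("solution", function(object) standardGeneric("solution"))
setMethod("solution", "LibraryOptimization", function(object) object@solution)

#' @rdname library-accessors
#' @export
setGeneric("paretoFront", function(object) standardGeneric("paretoFront"))
setMethod("paretoFront", "LibraryOptimization", function(object) object@pareto)

setMethod("show", "LibrarySolution", function(object) {
  cat(sprintf("LibrarySolution: %d positions, total error %s, size %s\n",
              length(object@labels), format(object@totalError),
              format(object@librarySize, big.mark = ",", scientific = FALSE)))
  for (i in seq_along(object@labels))
    cat(sprintf("  %-6s %s (error %s)\n", object@labels[i],
                paste(object@codonSets[[i]], collapse = ","),
                format(object@positionErrors[i])))
  if (!anyNA(object@primerCounts))
    cat(sprintf("  primers per stretch: %s (total %d)\n",
                paste(object@primerCounts, collapse = ", "),
                as.integer(object@primerTotal)))
})

setMethod("show", "LibraryOptimization", function(object) {
  cat(sprintf("LibraryOptimization (%s mode, diversity limit %s)\n",
              object@mode, format(object@diversityLimit, scientific = TRUE)))
  show(object@solution)
  cat(sprintf("  Pareto front: %d point%s (errors %s..%s)\n",
              nrow(object@pareto), if (nrow(object@pareto) == 1L) "" else "s",
              min(object@pareto$error), max(object@pareto$error)))
})
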