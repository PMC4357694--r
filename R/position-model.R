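# Per-position error model, codon-set evaluation, coverage-class reduction,
# and construction of the per-position smallest-size tables consumed by the
# dynamic programs.

#' Construct a position specification
#'
#' @param label position identifier (coerced to character).
#' @param counts named integer vector of observed amino-acid counts; names are
#'   one-letter codes (optionally `"*"` for STOP); missing symbols default to 0.
#' @param penalties named integer vector of penalties charged when the symbol
#'   is produced by the chosen codon set; defaults to 0 everywhere.
#' @param required symbols the chosen codon set (as a union) must produce.
#' @param forbidden symbols no chosen codon may produce.
#' @return a [PositionSpec-class].
#' @examples
#' positionSpec("269", c(A = 8, S = 44, T = 58, V = 49))
#' @export
positionSpec <- function(label, counts, penalties = NULL,
                         required = character(), forbidden = character()) {
  full <- function(v, what) {
    out <- stats::setNames(numeric(21L), AA_SYMBOLS)
    if (length(v)) {
      if (is.null(names(v)) || !all(names(v) %in% AA_SYMBOLS))
        stop(sprintf("%s must be named by amino-acid symbols", what))
      out[names(v)] <- as.numeric(v)
    }
    out
  }
  new("PositionSpec", label = as.character(label), counts = full(counts, "counts"),
      penalties = full(penalties, "penalties"),
      required = unique(as.character(required)),
      forbidden = unique(as.character(forbidden)))
}

# vectorized error over codons given by their coverage bitmasks:
# error = sum(counts) - sum_{covered} counts + sum_{covered} penalties
.maskErrors <- function(spec, aaMask) {
  err <- rep(sum(spec@counts), length(aaMask))
  delta <- spec@penalties - spec@counts
  for (b in which(delta != 0)) {
    hit <- bitwAnd(aaMask, bitwShiftL(1L, b - 1L)) != 0L
    err[hit] <- err[hit] + delta[b]
  }
  err
}

#' Error of a single degenerate codon at a position
#'
#' The sum of the counts of symbols the codon fails to produce, plus the
#' penalties of penalized symbols it does produce. Integer by construction.
#'
#' @param spec a [PositionSpec-class].
#' @param dc a [DegenerateCodon-class] or IUPAC string.
#' @param code genetic code.
#' @export
codonError <- function(spec, dc, code = standardGeneticCode()) {
  codonSetError(spec, list(dc), code = code)
}

#' Error of a set of degenerate codons at a position
#'
#' The error model applied to the union of the members' amino-acid sets;
#' penalties are charged once per penalized symbol present in the union.
#'
#' @param spec a [PositionSpec-class].
#' @param codons list/vector of codons (IUPAC strings or objects).
#' @param code genetic code.
#' @export
codonSetError <- function(spec, codons, code = standardGeneticCode()) {
  stopifnot(is(spec, "PositionSpec"), length(codons) >= 1L)
  covered <- aminoAcidSet(codons, code = code)
  sum(spec@counts[setdiff(AA_SYMBOLS, covered)]) + sum(spec@penalties[covered])
}

#' Combined DNA size of a codon set
#'
#' The sum of the members' degeneracies (mixed primers are synthesized
#' independently, so overlapping expansions still count with multiplicity).
#'
#' @param codons non-empty list/vector of distinct codons.
#' @export
codonSetSize <- function(codons) {
  stopifnot(length(codons) >= 1L)
  iupac <- vapply(codons, formatCodon, "")
  if (anyDuplicated(iupac)) stop("codon sets are duplicate-free")
  sum(vapply(codons, codonDegeneracy, 0))
}

# admissible codon indices into the universe (forbidden filter; optionally
# each codon must itself cover the required symbols)
.admissibleIdx <- function(spec, uni, requireCoverage = FALSE) {
  idx <- seq_along(uni$iupac)
  fmask <- .symbolMask(spec@forbidden)
  if (fmask != 0L) idx <- idx[bitwAnd(uni$aaMask[idx], fmask) == 0L]
  if (requireCoverage) {
    rmask <- .symbolMask(spec@required)
    if (rmask != 0L) idx <- idx[bitwAnd(uni$aaMask[idx], rmask) == rmask]
  }
  idx
}

#' Codons admissible at a position
#'
#' All degenerate codons whose amino-acid set contains no forbidden symbol.
#' With `requireCoverage = TRUE` (the single-codon setting) the codon must
#' additionally produce every required symbol itself; in multi-codon tables
#' required coverage is a property of the union, not of each member.
#'
#' @param spec a [PositionSpec-class].
#' @param requireCoverage logical.
#' @param code genetic code.
#' @return character vector of IUPAC codons.
#' @export
admissibleCodons <- function(spec, requireCoverage = FALSE,
                             code = standardGeneticCode()) {
  uni <- codonUniverse(code)
  idx <- .admissibleIdx(spec, uni, requireCoverage)
  if (!length(idx))
    stop(sprintf("position infeasible: no admissible codon at \"%s\"", spec@label))
  uni$iupac[idx]
}

# relevant symbols: contribute to the error by absence (counted) or presence
# (penalized), or are required (required coverage must survive reduction)
.relevantMask <- function(spec) {
  .symbolMask(AA_SYMBOLS[spec@counts > 0 | spec@penalties > 0 |
                           AA_SYMBOLS %in% spec@required])
}

#' Coverage-class representatives
#'
#' Groups admissible codons by their coverage signature -- the subset of
#' error-relevant symbols (positive count, positive penalty, or required)
#' present in their amino-acid set -- and keeps one minimal-degeneracy codon
#' per signature (ties broken toward the lexicographically smaller IUPAC
#' string). Codon-set optima computed over the representatives equal those
#' computed over the full admissible list, because error and required
#' coverage depend only on the signature and the set size is additive.
#'
#' @param spec a [PositionSpec-class].
#' @param codons optional character vector restricting the candidate codons
#'   (defaults to all admissible codons).
#' @param code genetic code.
#' @return character vector of representative IUPAC codons.
#' @export
coverageClassRepresentatives <- function(spec, codons = NULL,
                                         code = standardGeneticCode()) {
  uni <- codonUniverse(code)
  idx <- .admissibleIdx(spec, uni)
  if (!is.null(codons)) idx <- intersect(idx, match(toupper(codons), uni$iupac))
  rel <- .relevantMask(spec)
  sig <- bitwAnd(uni$aaMask[idx], rel)
  ord <- order(uni$deg[idx], idx)
  keep <- ord[!duplicated(sig[ord])]
  uni$iupac[sort(idx[keep])]
}

#' Build the per-position smallest-size table
#'
#' For every codon-set cardinality `j'` in `1..Lp` and every achievable error,
#' computes the minimal combined DNA size over unordered sets of exactly `j'`
#' distinct admissible codons whose translated union covers all required
#' symbols, with one witness set per entry (lexicographically smallest among
#' minimal-size sets). With `useReduction = TRUE` (default), sets of two or
#' more codons are enumerated over coverage-class representatives instead of
#' the full admissible list; the resulting table is identical.
#'
#' @param spec a [PositionSpec-class].
#' @param Lp maximum codons per position (>= 1).
#' @param useReduction use coverage-class reduction for the enumeration.
#' @param candidates optional character vector restricting candidate codons
#'   (used by the oracle-parity tests).
#' @param code genetic code.
#' @param budget maximum number of codon sets to enumerate before aborting.
#' @return a [PositionTable-class].
#' @export
buildPositionTable <- function(spec, Lp = 1L, useReduction = TRUE,
                               candidates = NULL, code = standardGeneticCode(),
                               budget = 5e8) {
  stopifnot(is(spec, "PositionSpec"), Lp >= 1L)
  Lp <- as.integer(Lp)
  uni <- codonUniverse(code)
  idx <- .admissibleIdx(spec, uni)
  if (!is.null(candidates)) {
    cidx <- match(toupper(candidates), uni$iupac)
    if (anyNA(cidx)) stop("unknown candidate codon")
    idx <- intersect(idx, cidx)
  }
  if (!length(idx))
    stop(sprintf("position infeasible: no admissible codon at \"%s\"", spec@label))

  rmask <- .symbolMask(spec@required)
  rows <- list()

  # exactly one codon: direct scan
  cov1 <- bitwAnd(uni$aaMask[idx], rmask) == rmask
  if (any(cov1)) {
    i1 <- idx[cov1]
    err1 <- .maskErrors(spec, uni$aaMask[i1])
    ord <- order(err1, uni$deg[i1], i1)
    keep <- ord[!duplicated(err1[ord])]
    rows[[1L]] <- data.frame(ncodons = 1L, error = err1[keep],
                             size = as.numeric(uni$deg[i1][keep]))
    rows[[1L]]$witness <- lapply(i1[keep], function(k) uni$iupac[k])
  }

  if (Lp >= 2L) {
    cand <- if (useReduction) {
      # up to Lp minimal-degeneracy codons per coverage class: a set may use
      # several same-signature codons (only ever dominated entries, but the
      # table stores them), so one representative per class is not enough
      rel <- .relevantMask(spec)
      sig <- bitwAnd(uni$aaMask[idx], rel)
      ord <- order(uni$deg[idx], idx)
      rank <- stats::ave(seq_along(ord), sig[ord], FUN = seq_along)
      sort(idx[ord[rank <= Lp]])
    } else sort(idx)
    n <- length(cand)
    ncombos <- sum(vapply(2:Lp, function(j) choose(n, j), 0))
    if (ncombos > budget)
      stop(sprintf("enumeration budget exceeded (%.3g sets > %.3g)", ncombos, budget))
    delta <- spec@penalties - spec@counts
    res <- cpp_enum_sets(uni$aaMask[cand], as.numeric(uni$deg[cand]),
                         as.numeric(sum(spec@counts)), as.numeric(delta),
                         rmask, Lp)
    for (j in seq_along(res)) {
      r <- res[[j]]
      if (!length(r$error)) next
      w <- lapply(seq_along(r$error), function(k)
        uni$iupac[cand[r$witness[[k]]]])
      df <- data.frame(ncodons = j + 1L, error = r$error, size = r$size)
      df$witness <- w
      rows[[length(rows) + 1L]] <- df
    }
  }

  if (!length(rows))
    stop(sprintf(
      "position infeasible: no codon set of size <= %d covers the required symbols at \"%s\"",
      Lp, spec@label))
  entries <- do.call(rbind, rows)
  entries <- entries[order(entries$ncodons, entries$error), , drop = FALSE]
  rownames(entries) <- NULL
  new("PositionTable", label = spec@label, Lp = Lp, entries = entries,
      maxError = as.integer(max(entries$error)))
}

# dense numeric matrix Lp x (maxError+1), NA = infeasible
.ptDense <- function(pt) {
  m <- matrix(NA_real_, nrow = pt@Lp, ncol = pt@maxError + 1L)
  e <- pt@entries
  m[cbind(e$ncodons, e$error + 1L)] <- e$size
  m
}

# witness lookup for (ncodons, error)
.ptWitness <- function(pt, j, e) {
  hit <- which(pt@entries$ncodons == j & pt@entries$error == e)
  if (!length(hit)) stop("no table entry for requested (ncodons, error)")
  pt@entries$witness[[hit[1L]]]
}

setMethod("show", "PositionSpec", function(object) {
  obs <- object@counts[object@counts > 0]
  cat(sprintf("PositionSpec \"%s\": %d observed symbol%s (%s)\n", object@label,
              length(obs), if (length(obs) == 1L) "" else "s",
              paste0(names(obs), "=", obs, collapse = " ")))
  if (length(object@required))
    cat("  required:", paste(object@required, collapse = ""), "\n")
  if (length(object@forbidden))
    cat("  forbidden:", paste(object@forbidden, collapse = ""), "\n")
  if (any(object@penalties > 0)) {
    p <- object@penalties[object@penalties > 0]
    cat("  penalties:", paste0(names(p), "=", p, collapse = " "), "\n")
  }
})

setMethod("show", "PositionTable", function(object) {
  cat(sprintf("PositionTable \"%s\": Lp = %d, %d entries, max error %d\n",
              object@label, object@Lp, nrow(object@entries), object@maxError))
})
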