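# Degenerate-codon algebra: IUPAC parsing/formatting, expansion, translation,
# degeneracy, and the enumeration of the full 3375-codon universe.

.dcopt_env <- new.env(parent = emptyenv())

.IUPAC_LETTERS <- sort(names(Biostrings::IUPAC_CODE_MAP))

# mask string ("ACGT" subsets, sorted) -> IUPAC letter
.MASK2LETTER <- local({
  m <- vapply(Biostrings::IUPAC_CODE_MAP, function(x)
    paste(sort(strsplit(x, "")[[1]]), collapse = ""), "")
  stats::setNames(names(m), unname(m))
})

#' The standard genetic code
#'
#' Named character vector mapping the 64 plain DNA codons to the 21 symbols of
#' [AA_SYMBOLS] (STOP as `"*"`). This is `Biostrings::GENETIC_CODE` and is the
#' default code everywhere; any complete 64-codon mapping onto the 21 symbols
#' can be supplied instead.
#'
#' @export
standardGeneticCode <- function() Biostrings::GENETIC_CODE

.checkGeneticCode <- function(code) {
  if (length(code) != 64L || is.null(names(code)))
    stop("a genetic code must map all 64 plain codons")
  if (!all(code %in% AA_SYMBOLS))
    stop("genetic code maps to an unknown symbol")
  invisible(code)
}

#' Parse a 3-letter IUPAC degenerate codon
#'
#' @param text a 3-character string over the 15 IUPAC degenerate-nucleotide
#'   letters (case-insensitive).
#' @return a [DegenerateCodon-class].
#' @examples
#' parseCodon("NNK")
#' @export
parseCodon <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("expected a single character string")
  s <- toupper(text)
  if (nchar(s) != 3L)
    stop(sprintf("a degenerate codon has exactly 3 letters, got \"%s\"", text))
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(ch, .IUPAC_LETTERS)
  if (length(bad))
    stop(sprintf("not an IUPAC nucleotide letter: \"%s\"", bad[1L]))
  masks <- lapply(ch, function(x)
    sort(strsplit(Biostrings::IUPAC_CODE_MAP[[x]], "")[[1]]))
  new("DegenerateCodon", masks = masks)
}

#' Format a degenerate codon as its canonical (uppercase) IUPAC string
#'
#' @param dc a [DegenerateCodon-class] (or an IUPAC string, returned
#'   canonicalized).
#' @export
formatCodon <- function(dc) {
  dc <- .asCodon(dc)
  paste(vapply(dc@masks, function(m)
    .MASK2LETTER[[paste(m, collapse = "")]], ""), collapse = "")
}

.asCodon <- function(x) {
  if (is(x, "DegenerateCodon")) x else parseCodon(x)
}

#' Degeneracy of a codon
#'
#' The number of plain DNA codons the degenerate codon expands to: the product
#' of its three nucleotide-set sizes, between 1 and 64.
#'
#' @param dc a [DegenerateCodon-class] or IUPAC string.
#' @examples
#' codonDegeneracy("NNN")  # 64
#' @export
codonDegeneracy <- function(dc) {
  dc <- .asCodon(dc)
  prod(lengths(dc@masks))
}

#' Expand a degenerate codon to its plain codons
#'
#' @param dc a [DegenerateCodon-class] or IUPAC string.
#' @return character vector of plain codons (cartesian product of the three
#'   nucleotide sets).
#' @examples
#' expandCodon("TRT")  # TAT, TGT
#' @export
expandCodon <- function(dc) {
  dc <- .asCodon(dc)
  m <- dc@masks
  as.vector(outer(outer(m[[1L]], m[[2L]], paste0), m[[3L]], paste0))
}

#' Amino acids produced by one or more degenerate codons
#'
#' Translates the expansion(s) under the genetic code and returns the set of
#' distinct symbols (amino acids and possibly `"*"` for STOP), sorted in
#' [AA_SYMBOLS] order. For several codons the union is returned.
#'
#' @param dc a [DegenerateCodon-class], an IUPAC string, or a list/vector of
#'   either (union taken).
#' @param code genetic code (see [standardGeneticCode()]).
#' @examples
#' aminoAcidSet("NDT")                 # 12 amino acids
#' aminoAcidSet(c("TRT", "TGG"))       # C, W, Y
#' @export
aminoAcidSet <- function(dc, code = standardGeneticCode()) {
  .checkGeneticCode(code)
  if (is(dc, "DegenerateCodon")) dc <- list(dc)
  plain <- unlist(lapply(dc, expandCodon), use.names = FALSE)
  aa <- unique(unname(code[plain]))
  AA_SYMBOLS[AA_SYMBOLS %in% aa]
}

#' Enumerate the full degenerate-codon universe
#'
#' All (2^4 - 1)^3 = 3375 degenerate codons, as IUPAC strings in lexicographic
#' order over the 15-letter IUPAC alphabet. This deterministic order is the
#' tie-breaking order used throughout the package.
#'
#' @return character vector of length 3375.
#' @export
allDegenerateCodons <- function() {
  codonUniverse()$iupac
}

# Internal cached universe: for a genetic code, a list with
#   iupac  : character(3375), lexicographic
#   deg    : integer(3375) degeneracies
#   aaMask : integer(3375) 21-bit coverage masks over AA_SYMBOLS
codonUniverse <- function(code = standardGeneticCode()) {
  cached <- .dcopt_env$universe
  if (!is.null(cached) && identical(cached$code, code))
    return(cached)
  .checkGeneticCode(code)
  g <- expand.grid(a = .IUPAC_LETTERS, b = .IUPAC_LETTERS, c = .IUPAC_LETTERS,
                   stringsAsFactors = FALSE)
  iupac <- paste0(g$a, g$b, g$c)
  ord <- order(iupac, method = "radix")
  iupac <- iupac[ord]

  nucs <- c("A", "C", "G", "T")
  # 0-based nucleotide indices per IUPAC letter
  letterIdx <- lapply(Biostrings::IUPAC_CODE_MAP,
                      function(x) match(strsplit(x, "")[[1]], nucs) - 1L)
  # amino-acid bit of each of the 64 plain codons, indexed 0..63 (a*16+b*4+c)
  plain <- as.vector(outer(outer(nucs, nucs, paste0), nucs, paste0))
  plainIdx <- (match(substr(plain, 1, 1), nucs) - 1L) * 16L +
    (match(substr(plain, 2, 2), nucs) - 1L) * 4L +
    (match(substr(plain, 3, 3), nucs) - 1L)
  aaBit <- integer(64L)
  aaBit[plainIdx + 1L] <- bitwShiftL(1L, match(unname(code[plain]), AA_SYMBOLS) - 1L)

  ch1 <- substr(iupac, 1, 1); ch2 <- substr(iupac, 2, 2); ch3 <- substr(iupac, 3, 3)
  deg <- lengths(letterIdx)[ch1] * lengths(letterIdx)[ch2] * lengths(letterIdx)[ch3]
  aaMask <- vapply(seq_along(iupac), function(k) {
    idx <- outer(outer(letterIdx[[ch1[k]]] * 16L, letterIdx[[ch2[k]]] * 4L, "+"),
                 letterIdx[[ch3[k]]], "+")
    Reduce(bitwOr, aaBit[idx + 1L], 0L)
  }, integer(1))

  uni <- list(code = code, iupac = iupac, deg = as.integer(unname(deg)),
              aaMask = aaMask)
  .dcopt_env$universe <- uni
  uni
}

# symbols -> 21-bit mask and back
.symbolMask <- function(symbols) {
  if (!length(symbols)) return(0L)
  Reduce(bitwOr, bitwShiftL(1L, match(symbols, AA_SYMBOLS) - 1L), 0L)
}

.maskSymbols <- function(mask) {
  AA_SYMBOLS[bitwAnd(bitwShiftR(mask, 0:20), 1L) == 1L]
}

setMethod("show", "DegenerateCodon", function(object) {
  cat(sprintf("DegenerateCodon %s (%d plain codon%s -> %s)\n",
              formatCodon(object), codonDegeneracy(object),
              if (codonDegeneracy(object) == 1L) "" else "s",
              paste(aminoAcidSet(object), collapse = "")))
})
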