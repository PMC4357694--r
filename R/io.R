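# Counts-table and configuration I/O, the packaged example problems, and the
# seeded fixture generator.

#' Read a counts table
#'
#' The table has a header row of position labels, a first column of symbols
#' (the 20 amino-acid one-letter codes plus an optional `"*"` row for STOP),
#' and non-negative integer cells: the number of times each symbol was
#' observed at each position among the input design sequences. Columns become
#' positions, in column order.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param penalties,required,forbidden optional per-position annotations:
#'   `penalties` a named numeric applied at every position, `required` /
#'   `forbidden` named lists (by position label) of symbol vectors.
#' @return list of [PositionSpec-class], one per column.
#' @export
readCountsTable <- function(path, dialect = c("tsv", "csv"), penalties = NULL,
                            required = list(), forbidden = list()) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (nrow(df) < 1L || ncol(df) < 2L) stop("empty counts table")
  syms <- df[[1L]]
  if (anyDuplicated(syms)) stop("duplicate symbol row in counts table")
  bad <- setdiff(syms, AA_SYMBOLS)
  if (length(bad)) stop(sprintf("unknown symbol row \"%s\"", bad[1L]))
  labs <- colnames(df)[-1L]
  if (anyDuplicated(labs)) stop("duplicate position label in counts table")
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df))
  if (anyNA(num) || any(num != floor(num)) || any(num < 0))
    stop("counts must be non-negative integers")
  lapply(seq_along(labs), function(j) {
    positionSpec(labs[j], stats::setNames(num[, j], syms),
                 penalties = penalties,
                 required = if (labs[j] %in% names(required))
                   required[[labs[j]]] else character(),
                 forbidden = if (labs[j] %in% names(forbidden))
                   forbidden[[labs[j]]] else character())
  })
}

#' Write a counts table
#'
#' Inverse of [readCountsTable()]: symbols with an all-zero row are kept so
#' that the round-trip is the identity on the 21-symbol grid.
#'
#' @param positions list of [PositionSpec-class].
#' @param path output file.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
writeCountsTable <- function(positions, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  labs <- .checkPositions(positions)
  m <- vapply(positions, function(p) p@counts, numeric(21L))
  df <- data.frame(symbol = AA_SYMBOLS, m, check.names = FALSE)
  colnames(df) <- c("symbol", labs)
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged example design problems
#'
#' Two bundled count tables from published directed-evolution design
#' campaigns, each derived from protein design simulations:
#' \describe{
#'   \item{`"interface"`}{nine surface positions of a protein-interface
#'     redesign (200 design trajectories), in two primer stretches.}
#'   \item{`"lov2"`}{twelve positions near the J-alpha helix of the
#'     *Avena sativa* LOV2 domain (1000 design trajectories), in five primer
#'     stretches; the native amino acid at each position is recorded so runs
#'     can require its coverage.}
#' }
#'
#' @param name `"interface"` or `"lov2"`.
#' @param requireNative for `"lov2"`, require the native amino acid at each
#'   position (default `TRUE`; `"interface"` has no native annotation).
#' @return list with `positions`, `layout`, and for `"lov2"` the named
#'   `natives` vector.
#' @export
exampleProblem <- function(name = c("interface", "lov2"), requireNative = TRUE) {
  name <- match.arg(name)
  if (name == "interface") {
    path <- system.file("extdata", "interface_design_counts.tsv",
                        package = "dcopt", mustWork = TRUE)
    list(positions = readCountsTable(path),
         layout = stretchLayout(list(
           c("268", "269", "270", "271", "272", "276"),
           c("330", "331", "332"))),
         natives = NULL)
  } else {
    path <- system.file("extdata", "lov2_design_counts.tsv",
                        package = "dcopt", mustWork = TRUE)
    natives <- c(`413` = "K", `475` = "E", `477` = "T", `479` = "Q",
                 `493` = "L", `495` = "H", `514` = "L", `520` = "V",
                 `528` = "G", `529` = "V", `531` = "L", `532` = "I")
    req <- if (requireNative) lapply(natives, identity) else list()
    list(positions = readCountsTable(path, required = req),
         layout = stretchLayout(list(
           "413", c("475", "477", "479"), c("493", "495"),
           c("514", "520"), c("528", "529", "531", "532"))),
         natives = natives)
  }
}

#' Generate a random counts-table fixture
#'
#' Emulates the count tables produced by protein design trajectories: at each
#' position a random subset of amino acids is observed, with multinomial
#' counts over a fixed total. Deterministic under `seed`; the caller's RNG
#' state is preserved.
#'
#' @param nPositions number of designable positions.
#' @param stretchSizes integer vector summing to `nPositions`: how the
#'   positions partition into primer stretches.
#' @param nSymbols distinct amino acids observed per position (recycled).
#' @param total total count per position (column sum; recycled).
#' @param seed integer seed.
#' @return list with `positions` (list of [PositionSpec-class]) and `layout`
#'   (a [StretchLayout-class]).
#' @export
generateFixture <- function(nPositions, stretchSizes = nPositions,
                            nSymbols = 4L, total = 100L, seed) {
  stopifnot(nPositions >= 1L, all(stretchSizes >= 1L),
            sum(stretchSizes) == nPositions, all(nSymbols >= 1L),
            all(total >= 1L))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  nSymbols <- rep_len(nSymbols, nPositions)
  total <- rep_len(total, nPositions)
  aa20 <- setdiff(AA_SYMBOLS, "*")
  positions <- lapply(seq_len(nPositions), function(i) {
    syms <- sample(aa20, nSymbols[i])
    repeat {  # multinomial draw conditioned on every chosen symbol observed
      cnt <- as.vector(stats::rmultinom(1L, total[i], rep(1, nSymbols[i])))
      if (all(cnt > 0) || total[i] < nSymbols[i]) break
    }
    positionSpec(as.character(i), stats::setNames(cnt, syms))
  })
  labs <- as.character(seq_len(nPositions))
  ends <- cumsum(stretchSizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  layout <- stretchLayout(lapply(seq_along(ends), function(k)
    labs[starts[k]:ends[k]]))
  list(positions = positions, layout = layout)
}

#' Read a run configuration
#'
#' YAML or JSON (by extension). Recognized fields: `counts` (path), `dialect`,
#' `stretches` (list of position-label lists), `limit` (diversity limit),
#' `max_codons_per_position`, `max_primers_per_stretch`,
#' `max_primers_total`, `penalties` (symbol -> integer), `required` /
#' `forbidden` (position label -> symbol list), `mode`, `out`, `report`,
#' `pareto`. Validation of values happens when the corresponding objects are
#' constructed; unknown fields are rejected here, naming the field.
#'
#' @param path config file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("counts", "dialect", "stretches", "limit",
             "max_codons_per_position", "max_primers_per_stretch",
             "max_primers_total", "penalties", "required", "forbidden",
             "mode", "out", "report", "pareto")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown configuration field \"%s\"", bad[1L]))
  cfg
}

#' Write a solution (and front) as JSON
#'
#' Codons as IUPAC strings; sizes as decimal integer strings so downstream
#' consumers cannot lose precision to 53-bit floats.
#'
#' @param opt a [LibraryOptimization-class].
#' @param path output file.
#' @export
writeSolutionJson <- function(opt, path) {
  stopifnot(is(opt, "LibraryOptimization"))
  sol <- opt@solution
  fmtInt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  obj <- list(
    positions = sol@labels,
    codons = sol@codonSets,
    positionErrors = sol@positionErrors,
    totalError = sol@totalError,
    librarySize = fmtInt(sol@librarySize),
    primersPerStretch = if (anyNA(sol@primerCounts)) NULL else
      sol@primerCounts,
    primersTotal = if (is.na(sol@primerTotal)) NULL else sol@primerTotal,
    diversityLimit = fmtInt(opt@diversityLimit),
    mode = opt@mode,
    pareto = list(error = opt@pareto$error, size = fmtInt(opt@pareto$size)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
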