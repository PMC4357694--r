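# Multi-codon dynamic program: primer accounting, limits, reduction to the
# single-codon program, and oracle parity.

test_that("primer counts are per-stretch products of codon counts", {
  p1 <- interfaceProblem()
  sol3 <- evaluateLibrary(p1$positions, interfaceThreeCodonSets(),
                          layout = p1$layout)
  pc <- countPrimers(sol3, p1$layout)
  expect_equal(unname(pc$perStretch), c(9, 6))
  expect_equal(pc$total, 15)

  p2 <- lov2Problem()
  sol <- evaluateLibrary(p2$positions, lov2ThreeCodonSets(),
                         layout = p2$layout)
  expect_equal(countPrimers(sol, p2$layout)$total, 24)

  # all-singleton solutions need one primer per stretch
  single <- optimizeSingle(p1$positions, "3.2e8", layout = p1$layout)
  expect_equal(countPrimers(solution(single), p1$layout)$total,
               length(p1$layout@stretches))
})

test_that("with one codon per position the multi DP equals the single DP", {
  for (seed in c(3, 14, 15)) {
    fx <- smallFixture(seed, nPositions = 3L, stretchSizes = c(2L, 1L),
                       nSymbols = 3L, total = 15L, k = 8L)
    tabs <- lapply(seq_len(3L), function(i)
      buildPositionTable(fx$positions[[i]], Lp = 1L,
                         candidates = fx$candidates[[i]]))
    s <- optimizeSingle(fx$positions, 500, tables = tabs)
    m <- optimizeMulti(fx$positions, fx$layout, 500,
                       primerLimits(Lp = 1, LT = 4), tables = tabs)
    expect_equal(totalError(m), totalError(s))
    expect_equal(librarySize(m), librarySize(s))
  }
})

test_that("multi-codon optimum matches exhaustive search on small fixtures", {
  for (seed in 101:106) {
    fx <- smallFixture(seed, nPositions = 3L, stretchSizes = c(2L, 1L),
                       nSymbols = 3L, total = 12L, k = 5L)
    lim <- primerLimits(Lp = 2, LT = 6, Ls = 4)
    limit <- c(50, 400, 4000)[(seed %% 3) + 1]
    res <- try(optimizeMulti(fx$positions, fx$layout, limit, lim,
                             candidates = fx$candidates), silent = TRUE)
    bf <- try(bruteForceOptimize(fx$positions, limit, fx$candidates,
                                 layout = fx$layout, limits = lim),
              silent = TRUE)
    if (inherits(bf, "try-error")) {
      expect_s3_class(res, "try-error")
    } else {
      expect_equal(totalError(res), bf$error)
      expect_equal(librarySize(res), bf$size)
    }
  }
})

test_that("solutions respect every primer limit and self-recompute", {
  fx <- smallFixture(77, nPositions = 4L, stretchSizes = c(2L, 2L),
                     nSymbols = 4L, total = 20L, k = 6L)
  lim <- primerLimits(Lp = 2, LT = 5, Ls = 4)
  res <- optimizeMulti(fx$positions, fx$layout, 1e6, lim,
                       candidates = fx$candidates)
  sol <- solution(res)
  pc <- countPrimers(sol, fx$layout)
  expect_true(all(pc$perStretch <= lim@Ls))
  expect_lte(pc$total, lim@LT)
  expect_true(all(lengths(codonSets(sol)) <= lim@Lp))
  expect_equal(pc$total, sol@primerTotal)
  reErr <- sum(vapply(seq_len(4L), function(i)
    codonSetError(fx$positions[[i]], sol@codonSets[[i]]), 0))
  expect_equal(reErr, totalError(res))
  expect_equal(prod(vapply(sol@codonSets, codonSetSize, 0)),
               librarySize(res))
})

test_that("relaxing any limit never raises the optimal error", {
  fx <- smallFixture(88, nPositions = 3L, stretchSizes = c(2L, 1L),
                     nSymbols = 4L, total = 20L, k = 6L)
  base <- list(L = 300, Lp = 1L, Ls = 2L, LT = 3L)
  err <- function(L, Lp, Ls, LT)
    totalError(optimizeMulti(fx$positions, fx$layout, L,
                             primerLimits(Lp = Lp, LT = LT, Ls = Ls),
                             candidates = fx$candidates))
  e0 <- err(base$L, base$Lp, base$Ls, base$LT)
  expect_lte(err(base$L * 50, base$Lp, base$Ls, base$LT), e0)
  expect_lte(err(base$L, 2L, base$Ls, base$LT), e0)
  expect_lte(err(base$L, base$Lp, 4L, 4L), e0)
  expect_lte(err(base$L, base$Lp, base$Ls, 6L), e0)
})

test_that("limit objects enforce their invariants", {
  expect_error(primerLimits(Lp = 3, LT = 2), "Lp <= Ls <= LT")
  expect_error(primerLimits(Lp = 0, LT = 2), "positive")
  p1 <- interfaceProblem()
  expect_error(
    optimizeMulti(p1$positions, p1$layout, "3.2e8",
                  primerLimits(Lp = 1, LT = 1)),
    "per stretch")
  # layout must partition the positions contiguously
  badLayout <- stretchLayout(list(c("268", "270"), c("269")))
  expect_error(
    optimizeMulti(p1$positions[1:3], badLayout, "1e6",
                  primerLimits(Lp = 1, LT = 2)),
    "contiguous")
})

test_that("multiple codons recover amino-acid sets one codon cannot", {
  # {C,W,Y} with STOP forbidden is only designable with two codons
  spec <- positionSpec("1", c(C = 5, W = 5, Y = 5),
                       required = c("C", "W", "Y"), forbidden = "*")
  layout <- stretchLayout(list("1"))
  res <- optimizeMulti(list(spec), layout, 64, primerLimits(Lp = 2, LT = 2))
  expect_equal(totalError(res), 0)
  expect_equal(librarySize(res), 3)
  w <- codonSets(res)[["1"]]
  expect_length(w, 2)
  expect_true(all(c("C", "W", "Y") %in% aminoAcidSet(w)))
  expect_false("*" %in% aminoAcidSet(w))
})
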