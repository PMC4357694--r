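# Single-codon dynamic program: optimum, traceback, Pareto front.

test_that("a one-position problem returns that position's best codon", {
  spec <- positionSpec("1", c(C = 5, W = 2, Y = 9))
  res <- optimizeSingle(list(spec), 64)
  pt <- buildPositionTable(spec, Lp = 1L)
  feas <- pt@entries[pt@entries$size <= 64, , drop = FALSE]
  expect_equal(totalError(res), min(feas$error))
  expect_identical(codonSets(res)[["1"]],
                   dcopt:::.ptWitness(pt, 1L, totalError(res)))
})

test_that("optimum matches exhaustive search on small seeded fixtures", {
  for (seed in 1:8) {
    fx <- smallFixture(seed, nPositions = 3L, nSymbols = 3L, total = 15L,
                       k = 8L)
    tabs <- lapply(seq_len(3L), function(i)
      buildPositionTable(fx$positions[[i]], Lp = 1L,
                         candidates = fx$candidates[[i]]))
    limit <- c(30, 200, 5000)[(seed %% 3) + 1]
    res <- try(optimizeSingle(fx$positions, limit, tables = tabs),
               silent = TRUE)
    bf <- try(bruteForceOptimize(fx$positions, limit, fx$candidates),
              silent = TRUE)
    if (inherits(bf, "try-error")) {
      expect_s3_class(res, "try-error")
    } else {
      expect_equal(totalError(res), bf$error)
      expect_equal(librarySize(res), bf$size)
    }
  }
})

test_that("traceback reproduces the reported error and size exactly", {
  fx <- smallFixture(21, nPositions = 4L, nSymbols = 4L, total = 25L, k = 8L)
  tabs <- lapply(seq_len(4L), function(i)
    buildPositionTable(fx$positions[[i]], Lp = 1L,
                       candidates = fx$candidates[[i]]))
  res <- optimizeSingle(fx$positions, 1e5, tables = tabs)
  sol <- solution(res)
  reErr <- sum(vapply(seq_len(4L), function(i)
    codonSetError(fx$positions[[i]], sol@codonSets[[i]]), 0))
  reSize <- prod(vapply(sol@codonSets, codonSetSize, 0))
  expect_equal(reErr, totalError(res))
  expect_equal(reSize, librarySize(res))
})

test_that("raising the diversity limit never raises the optimal error", {
  fx <- smallFixture(33, nPositions = 3L, nSymbols = 4L, total = 20L, k = 10L)
  tabs <- lapply(seq_len(3L), function(i)
    buildPositionTable(fx$positions[[i]], Lp = 1L,
                       candidates = fx$candidates[[i]]))
  errs <- vapply(c(10, 100, 1000, 1e5), function(L)
    totalError(optimizeSingle(fx$positions, L, tables = tabs)), 0)
  expect_true(all(diff(errs) <= 0))
})

test_that("full-table and output-sensitive modes agree on the optimum", {
  fx <- smallFixture(44, nPositions = 3L, nSymbols = 3L, total = 12L, k = 8L)
  tabs <- lapply(seq_len(3L), function(i)
    buildPositionTable(fx$positions[[i]], Lp = 1L,
                       candidates = fx$candidates[[i]]))
  lazy <- optimizeSingle(fx$positions, 100, tables = tabs)
  full <- optimizeSingle(fx$positions, 100, mode = "full-table", tables = tabs)
  expect_equal(totalError(lazy), totalError(full))
  expect_equal(librarySize(lazy), librarySize(full))
  # the lazy front is a prefix of the full front
  expect_true(max(paretoFront(lazy)$error) <= max(paretoFront(full)$error))
  common <- min(nrow(paretoFront(lazy)), nrow(paretoFront(full)))
  expect_equal(paretoFront(lazy)[seq_len(common), ],
               paretoFront(full)[seq_len(common), ])
  # output-sensitive exploration stops at the optimum's error level
  expect_equal(max(paretoFront(lazy)$error), totalError(lazy))
})

test_that("the Pareto front is strictly dominated-point free", {
  p1 <- interfaceProblem()
  res <- optimizeSingle(p1$positions, "3.2e8", mode = "full-table")
  front <- paretoFront(res)
  expect_true(all(diff(front$error) > 0))
  expect_true(all(diff(front$size) < 0))
  expect_equal(min(front$error[front$size <= 3.2e8]), totalError(res))
})

test_that("an impossible size limit reports no feasible library", {
  # covering both F and W with one codon needs at least 4 DNA sequences
  spec <- positionSpec("1", c(F = 5, W = 5), required = c("F", "W"))
  expect_error(optimizeSingle(list(spec), 3), "no feasible library")
  res <- optimizeSingle(list(spec), 4)
  expect_equal(librarySize(res), 4)
})

test_that("diversity limits in scientific notation are floored exactly", {
  expect_identical(parseDiversityLimit("3.2e8"), 3.2e8)
  expect_identical(parseDiversityLimit("1e9"), 1e9)
  expect_identical(parseDiversityLimit(10.7), 10)
  expect_error(parseDiversityLimit("nope"), "positive")
  expect_error(parseDiversityLimit(0), "positive")
})
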