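# Position error model, codon-set evaluation, admissibility, coverage-class
# reduction and the per-position smallest-size tables.

test_that("single-codon errors match published per-position values", {
  p1 <- interfaceProblem()$positions
  names(p1) <- vapply(p1, function(p) p@label, "")
  expect_equal(codonError(p1[["269"]], "RBT"), 39)
  expect_equal(codonError(p1[["272"]], "DYG"), 1)
  p2 <- lov2Problem(requireNative = FALSE)$positions
  names(p2) <- vapply(p2, function(p) p@label, "")
  expect_equal(codonError(p2[["514"]], "WDS"), 47)
  # a codon covering every counted symbol has zero error without penalties
  expect_equal(codonError(positionSpec("x", c(C = 5, W = 2, Y = 9)), "TRK"), 0)
})

test_that("codon-set errors use the union of amino-acid sets", {
  p2 <- lov2Problem(requireNative = FALSE)$positions
  names(p2) <- vapply(p2, function(p) p@label, "")
  expect_equal(codonSetError(p2[["529"]], c("CWC", "RBG")), 1)
  p1 <- interfaceProblem()$positions
  names(p1) <- vapply(p1, function(p) p@label, "")
  expect_equal(codonSetError(p1[["269"]], c("DBG", "RAM")), 4)
  expect_equal(codonSetError(p1[["269"]], "RBT"), codonError(p1[["269"]], "RBT"))
})

test_that("penalties are charged once per penalized symbol in the union", {
  spec <- positionSpec("x", c(C = 5, W = 2, Y = 9), penalties = c(`*` = 7))
  expect_equal(codonError(spec, "TRK"), 7)          # TRK pulls in STOP
  expect_equal(codonSetError(spec, c("TRT", "TGG")), 0)
  # two STOP-producing codons still pay the penalty once
  expect_equal(codonSetError(spec, c("TRK", "TAR")), 7)
})

test_that("codon-set size sums member degeneracies and rejects duplicates", {
  expect_equal(codonSetSize(c("TRT", "TGG")), 3)
  expect_equal(codonSetSize(c("DBG", "RAM")), 13)
  expect_equal(codonSetSize("VDR"), codonDegeneracy("VDR"))
  expect_error(codonSetSize(c("TRT", "TRT")), "duplicate")
})

test_that("admissibility filters forbidden and (optionally) required symbols", {
  spec <- positionSpec("x", c(A = 1), forbidden = "*")
  adm <- admissibleCodons(spec)
  stops <- c("TAA", "TAG", "TGA")
  expect_false(any(vapply(adm, function(cd)
    any(expandCodon(cd) %in% stops), TRUE)))
  specK <- positionSpec("413", c(A = 990, F = 1, G = 9), required = "K")
  admK <- admissibleCodons(specK, requireCoverage = TRUE)
  expect_true("RMA" %in% admK)
  expect_true(all(vapply(admK, function(cd) "K" %in% aminoAcidSet(cd), TRUE)))
  free <- positionSpec("y", c(A = 1))
  expect_length(admissibleCodons(free), 3375)
  # forbidding everything leaves no admissible codon
  expect_error(
    admissibleCodons(positionSpec("z", counts = NULL,
                                  forbidden = AA_SYMBOLS)),
    "position infeasible")
})

test_that("coverage classes collapse to covered/not-covered for one symbol", {
  spec <- positionSpec("x", c(W = 10))
  reps <- coverageClassRepresentatives(spec)
  expect_length(reps, 2)
  covers <- vapply(reps, function(cd) "W" %in% aminoAcidSet(cd), TRUE)
  expect_setequal(covers, c(TRUE, FALSE))
  # the representatives are minimal: degeneracy 1 in both classes
  expect_equal(unname(vapply(reps, codonDegeneracy, 0)), c(1, 1))
})

test_that("representative sets on the bundled problems are small", {
  sizes <- vapply(c(interfaceProblem()$positions, lov2Problem()$positions),
                  function(p) length(coverageClassRepresentatives(p)), 0L)
  # a tiny fraction of the 3375-codon universe: enumeration over
  # representatives is what makes multi-codon tables affordable
  expect_true(all(sizes < 500))
  expect_true(all(sizes >= 2))
  expect_gte(sum(sizes >= 100), 5)
})

test_that("single-codon table equals a direct scan over admissible codons", {
  p1 <- interfaceProblem()$positions
  spec <- p1[[4]]  # position 271
  pt <- buildPositionTable(spec, Lp = 1L)
  expect_equal(pt@entries$size[pt@entries$error == 6], 2)
  # direct scan oracle
  adm <- admissibleCodons(spec, requireCoverage = TRUE)
  err <- vapply(adm, function(cd) codonError(spec, cd), 0)
  deg <- vapply(adm, codonDegeneracy, 0)
  direct <- tapply(deg, err, min)
  got <- stats::setNames(pt@entries$size, pt@entries$error)
  expect_equal(unname(got), as.numeric(direct[names(got)]))
  expect_setequal(names(got), names(direct))
  # every witness recomputes to its stored (error, size)
  for (r in seq_len(nrow(pt@entries))) {
    w <- pt@entries$witness[[r]]
    expect_equal(codonSetError(spec, w), pt@entries$error[r])
    expect_equal(codonSetSize(w), pt@entries$size[r])
  }
})

test_that("tables with and without reduction are identical", {
  fx <- smallFixture(101, nPositions = 1L, nSymbols = 2L, total = 10L)
  spec <- fx$positions[[1]]
  with_red <- buildPositionTable(spec, Lp = 2L, useReduction = TRUE)
  without <- buildPositionTable(spec, Lp = 2L, useReduction = FALSE)
  expect_equal(with_red@entries[c("ncodons", "error", "size")],
               without@entries[c("ncodons", "error", "size")])
})

test_that("pair tables equal brute-force enumeration on small alphabets", {
  for (seed in c(7, 8, 9)) {
    fx <- smallFixture(seed, nPositions = 1L, nSymbols = 3L, total = 12L,
                       k = 10L)
    spec <- fx$positions[[1]]
    cand <- fx$candidates[[1]]
    pt <- buildPositionTable(spec, Lp = 2L, candidates = cand)
    bf <- bruteForcePositionTable(spec, Lp = 2L, candidates = cand)
    expect_equal(pt@entries[c("ncodons", "error", "size")],
                 bf@entries[c("ncodons", "error", "size")])
    expect_identical(pt@entries$witness, bf@entries$witness)
  }
})

test_that("multi-codon entries cover required symbols as a union", {
  spec <- positionSpec("x", c(C = 1, W = 1, Y = 1), required = c("C", "W", "Y"),
                       forbidden = "*")
  # no single codon covers {C,W,Y} without STOP; two can (TGG + TRT, size 3)
  expect_error(buildPositionTable(spec, Lp = 1L), "position infeasible")
  pt <- buildPositionTable(spec, Lp = 2L)
  zero <- pt@entries[pt@entries$error == 0, , drop = FALSE]
  expect_equal(zero$ncodons, 2L)
  expect_equal(zero$size, 3)
  w <- zero$witness[[1]]
  expect_true(all(c("C", "W", "Y") %in% aminoAcidSet(w)))
  expect_false("*" %in% aminoAcidSet(w))
  expect_equal(codonSetSize(w), 3)
})

test_that("stored minimal sizes shrink (weakly) as allowed error grows", {
  fx <- smallFixture(55, nPositions = 1L, nSymbols = 4L, total = 30L)
  pt <- buildPositionTable(fx$positions[[1]], Lp = 2L)
  for (j in 1:2) {
    e <- pt@entries[pt@entries$ncodons == j, , drop = FALSE]
    run <- cummin(e$size[order(e$error)])
    # after dominance pruning, the running minimum is what the DP consumes
    expect_true(all(diff(run) <= 0))
  }
})

test_that("a positive-count symbol cannot be forbidden", {
  expect_error(positionSpec("x", c(A = 3), forbidden = "A"), "forbidden")
  expect_error(positionSpec("x", c(A = 3), required = "K", forbidden = "K"),
               "required and forbidden")
  expect_error(positionSpec("x", c(A = -1)), "non-negative")
  expect_error(positionSpec("x", c(A = 1.5)), "non-negative")
})
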