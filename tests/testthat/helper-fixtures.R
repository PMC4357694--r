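# Shared helpers: bundled problems, printed reference assignments, and small
# seeded fixtures with deterministic candidate restrictions for oracle-parity
# tests.

interfaceProblem <- function() exampleProblem("interface")
lov2Problem <- function(requireNative = TRUE)
  exampleProblem("lov2", requireNative = requireNative)

# expert manual assignments for the two bundled problems (as published),
# including for the LOV2 library the native codon at each position and the
# intended leucine codon CTG at position 520
interfaceManualSets <- function() {
  list(`268` = "VDR", `269` = "RBT", `270` = "RYY", `271` = "KCT",
       `272` = "RBT", `276` = "RVT", `330` = "RVW", `331` = "VNW",
       `332` = "VVW")
}

lov2ManualSets <- function() {
  list(`413` = c("GCC", "AAA"), `475` = c("ARA", "GAG"),
       `477` = c("KGG", "YWC", "ACC"), `479` = c("RBA", "CAG"),
       `493` = c("SNC", "TTG"), `495` = c("KKC", "CAT"),
       `514` = c("DDC", "WKG", "CTG"), `520` = c("CTG", "GTG"),
       `528` = c("RYG", "GGG"), `529` = c("CDT", "RYG", "GTG"),
       `531` = c("WGG", "CTG"), `532` = c("GCC", "ATT"))
}

# three-codon interface solution as published (9 + 6 = 15 primers)
interfaceThreeCodonSets <- function() {
  list(`268` = c("MKC", "RYG", "VAM"), `269` = c("AKS", "RMC", "SWA"),
       `270` = "DYA", `271` = "DCA", `272` = "DYG", `276` = "RSC",
       `330` = c("ADG", "RVC", "SAA"), `331` = c("DBG", "VAM"),
       `332` = "VNS")
}

# three-codon LOV2 solution as published (3 + 6 + 4 + 3 + 8 = 24 primers)
lov2ThreeCodonSets <- function() {
  list(`413` = c("AAA", "GSA", "TTC"), `475` = "RVA",
       `477` = c("DBG", "HWC"), `479` = c("ATA", "CAA", "GSA"),
       `493` = c("ATR", "SNC"), `495` = c("GSA", "YWC"),
       `514` = c("ATR", "KGG", "YWC"), `520` = "VTG",
       `528` = c("ATG", "GSA"), `529` = c("DKG", "SMC"), `531` = "WKG",
       `532` = c("ATR", "GYA"))
}

# deterministic per-position candidate restriction: the lexicographically
# first k coverage-class representatives (applied identically to the DP under
# test and to the brute-force oracle)
restrictCandidates <- function(spec, k) {
  utils::head(coverageClassRepresentatives(spec), k)
}

smallFixture <- function(seed, nPositions = 3L, stretchSizes = nPositions,
                         nSymbols = 3L, total = 20L, k = 8L) {
  fx <- generateFixture(nPositions, stretchSizes, nSymbols, total, seed = seed)
  fx$candidates <- lapply(fx$positions, restrictCandidates, k = k)
  fx
}
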