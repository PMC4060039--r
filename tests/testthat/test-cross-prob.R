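fx <- buildAlbatrossFixture()

test_that("the canonical genotype reproduces all six cross probabilities", {
  g <- fx$genotype
  expect_equal(genotypeProbGivenCross(g, "F1_motherA", fx$panel), 0.90)
  expect_identical(genotypeProbGivenCross(g, "F1_motherB", fx$panel), 0)
  expect_equal(genotypeProbGivenCross(g, "BC_F1female_x_Bmale", fx$panel),
    0.45 * 0.5^4)
  expect_equal(genotypeProbGivenCross(g, "BC_F1female_x_Amale", fx$panel),
    0.03375)
  expect_equal(genotypeProbGivenCross(g, "BC_F1male_x_Afemale", fx$panel),
    0.03375)
  expect_identical(
    genotypeProbGivenCross(g, "BC_F1male_x_Bfemale", fx$panel), 0)
})

test_that("fully fixed markers force heterozygosity in F1s", {
  pan <- MarkerPanel(
    freqA = list(m1 = c(A = 1), m2 = c(C = 1)),
    freqB = list(m1 = c(G = 1), m2 = c(`T` = 1)))
  het <- MultilocusGenotype("h",
    list(m1 = c("A", "G"), m2 = c("C", "T")), mtdna = "A")
  expect_identical(genotypeProbGivenCross(het, "F1_motherA", pan), 1)
  hetB <- MultilocusGenotype("h",
    list(m1 = c("A", "G"), m2 = c("C", "T")), mtdna = "B")
  expect_identical(genotypeProbGivenCross(hetB, "F1_motherB", pan), 1)
  # unknown mtDNA omits the maternal factor
  hetU <- MultilocusGenotype("h",
    list(m1 = c("A", "G"), m2 = c("C", "T")), mtdna = "unknown")
  expect_identical(genotypeProbGivenCross(hetU, "F1_motherB", pan), 1)
})

test_that("probabilities over all genotypes and mtDNA states sum to 1", {
  pan <- toyPanel()
  alleles <- lapply(markerIds(pan), function(mk)
    union(names(alleleFreq(pan, mk, "A")), names(alleleFreq(pan, mk, "B"))))
  names(alleles) <- markerIds(pan)
  for (cross in crossClasses()) {
    tot <- 0
    for (p1 in allPairs(alleles$m1)) {
      for (p2 in allPairs(alleles$m2)) {
        for (mt in c("A", "B")) {
          g <- MultilocusGenotype("e", list(m1 = p1, m2 = p2), mtdna = mt)
          tot <- tot + genotypeProbGivenCross(g, cross, pan)
        }
      }
    }
    expect_equal(tot, 1, tolerance = 1e-12, label = cross)
  }
})

test_that("F1 probability equals the closed-form per-marker product", {
  pan <- toyPanel()
  g <- MultilocusGenotype("h", list(m1 = c("A", "G"), m2 = c("A", "G")),
    mtdna = "A")
  # m1: fixed difference -> het A/G with prob 1
  # m2: dam A-gamete {A:.7,G:.3}, sire B-gamete {G:.8,T:.2};
  # unordered (A,G): .7*.8 + .3*0 = .56
  expect_equal(genotypeProbGivenCross(g, "F1_motherA", pan), 1 * 0.56)
})

test_that("posterior classification reproduces the 0.904 F1 posterior", {
  cls <- c("F1_motherA", "BC_F1female_x_Bmale", "BC_F1female_x_Amale",
    "BC_F1male_x_Afemale")
  out <- classifyHybrid(fx$genotype, fx$panel, cls)
  expect_equal(out$class[1], "F1_motherA")
  expect_equal(out$posterior[1],
    0.90 / (0.90 + 0.028125 + 0.03375 + 0.03375), tolerance = 1e-12)
  expect_equal(round(out$posterior[1], 3), 0.904)
  expect_equal(sum(out$posterior), 1)
})

test_that("pure genotypes classify deterministically under fixed panels", {
  pureB <- MultilocusGenotype("pb", list(MHC = c("G", "G"),
    `1FWD` = c("C", "C"), `1REV` = c("TGC", "TGC"), `4FWD` = c("T", "T"),
    `4REV` = c("C", "C")), mtdna = "B")
  out <- classifyHybrid(pureB, fx$panel, "PURE_B")
  expect_identical(out$probability, 1)
  expect_identical(out$posterior, 1)
})

test_that("an impossible genotype yields an explicit inconsistent result", {
  het <- MultilocusGenotype("h", list(MHC = c("A", "G"),
    `1FWD` = c("A", "C"), `1REV` = c("CAG", "TGC"), `4FWD` = c("C", "T"),
    `4REV` = c("A", "C")), mtdna = "B")
  # B mtDNA with a genotype only producible with an A dam among these classes
  out <- classifyHybrid(het, fx$panel, c("PURE_A", "F1_motherA"))
  expect_true(all(out$probability == 0))
  expect_true(all(is.na(out$posterior)))
  expect_true(isTRUE(attr(out, "inconsistent")))
})

test_that("swapping species labels swaps the reciprocal F1 probabilities", {
  swapped <- swapSpecies(fx$panel)
  gA <- fx$genotype   # het everywhere, mtDNA from the species-A dam
  gB <- MultilocusGenotype(sampleId(gA), list(MHC = c("A", "G"),
    `1FWD` = c("A", "C"), `1REV` = c("CAG", "TGC"), `4FWD` = c("C", "T"),
    `4REV` = c("A", "C")), mtdna = "B")
  # the same biological cross (LA dam x BF sire) is F1_motherB after the swap
  expect_equal(genotypeProbGivenCross(gB, "F1_motherB", swapped),
    genotypeProbGivenCross(gA, "F1_motherA", fx$panel))
  expect_identical(genotypeProbGivenCross(gB, "F1_motherA", swapped), 0)
})

test_that("unknown cross class and bad maternal label raise errors", {
  expect_error(genotypeProbGivenCross(fx$genotype, "F3", fx$panel),
    "unknown cross class")
  expect_error(genotypeProbGivenCross(fx$genotype, "F2", fx$panel,
    f1Maternal = "C"), "f1Maternal")
  expect_error(classifyHybrid(fx$genotype, fx$panel, character(0)),
    "non-empty")
})
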