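fx <- buildAlbatrossFixture()

test_that("diagnostic index scores the canonical genotype 0.5091", {
  expect_equal(diagnosticIndex(fx$genotype, fx$panel), 0.509090909,
    tolerance = 1e-8)
  expect_equal(round(diagnosticIndex(fx$genotype, fx$panel), 2), 0.51)
})

test_that("pure parental genotypes score exactly 1 and 0", {
  pureA <- MultilocusGenotype("pa", list(MHC = c("A", "A"),
    `1FWD` = c("A", "A"), `1REV` = c("CAG", "CAG"), `4FWD` = c("C", "C"),
    `4REV` = c("A", "A")), mtdna = "A")
  pureB <- MultilocusGenotype("pb", list(MHC = c("G", "G"),
    `1FWD` = c("C", "C"), `1REV` = c("TGC", "TGC"), `4FWD` = c("T", "T"),
    `4REV` = c("C", "C")), mtdna = "B")
  expect_identical(diagnosticIndex(pureA, fx$panel), 1)
  # shared polymorphism: the B allele has nonzero posterior of A origin,
  # so only the orientation-0 species is exactly 0 at fixed markers;
  # pure B is homozygous for alleles absent from A except at 1FWD
  expect_equal(diagnosticIndex(pureB, fx$panel),
    (0 * 8 + 2 * (0.1 / 1.1)) / 10, tolerance = 1e-12)
  expect_identical(diagnosticIndex(pureA, fx$panel, orientation = "B1"), 0)
})

test_that("homozygous-B at the shared marker gives the derived 0.4182", {
  g <- MultilocusGenotype("g", list(MHC = c("A", "G"),
    `1FWD` = c("C", "C"), `1REV` = c("CAG", "TGC"), `4FWD` = c("C", "T"),
    `4REV` = c("A", "C")), mtdna = "A")
  expect_equal(diagnosticIndex(g, fx$panel),
    (4 * 0.5 + (0.0909090909 + 0.0909090909) / 2) / 5, tolerance = 1e-8)
})

test_that("index is invariant to marker order and flips under orientation", {
  alleles <- list(`4REV` = c("A", "C"), MHC = c("A", "G"),
    `1REV` = c("CAG", "TGC"), `1FWD` = c("A", "C"), `4FWD` = c("C", "T"))
  g2 <- MultilocusGenotype("perm", alleles, mtdna = "A")
  expect_equal(diagnosticIndex(g2, fx$panel),
    diagnosticIndex(fx$genotype, fx$panel))
  expect_equal(diagnosticIndex(fx$genotype, fx$panel, orientation = "B1"),
    1 - diagnosticIndex(fx$genotype, fx$panel))
})

test_that("swapping panel species maps the index to 1 - x", {
  swapped <- swapSpecies(fx$panel)
  expect_equal(diagnosticIndex(fx$genotype, swapped),
    1 - diagnosticIndex(fx$genotype, fx$panel))
})

test_that("an allele absent from both panels raises a named error", {
  g <- MultilocusGenotype("bad", list(MHC = c("A", "T"),
    `1FWD` = c("A", "C"), `1REV` = c("CAG", "TGC"), `4FWD` = c("C", "T"),
    `4REV` = c("A", "C")), mtdna = "A")
  expect_error(diagnosticIndex(g, fx$panel), "MHC")
})

test_that("ML index is 0.5 by symmetry for fully heterozygous fixed markers", {
  pan <- MarkerPanel(
    freqA = list(m1 = c(A = 1), m2 = c(C = 1)),
    freqB = list(m1 = c(G = 1), m2 = c(`T` = 1)))
  g <- MultilocusGenotype("h", list(m1 = c("A", "G"), m2 = c("C", "T")))
  r <- mlHybridIndex(g, pan)
  expect_equal(r$h, 0.5, tolerance = 1e-5)
})

test_that("ML index hits the boundary for a pure genotype", {
  pan <- MarkerPanel(
    freqA = list(m1 = c(A = 1), m2 = c(C = 1)),
    freqB = list(m1 = c(G = 1), m2 = c(`T` = 1)))
  g <- MultilocusGenotype("pa", list(m1 = c("A", "A"), m2 = c("C", "C")))
  r <- mlHybridIndex(g, pan)
  expect_identical(r$h, 1)
  expect_identical(r$ciHigh, 1)
  expect_lt(r$ciLow, 1)
})

test_that("ML index equals the dense grid-search oracle", {
  expect_equal(mlHybridIndex(fx$genotype, fx$panel)$h,
    oracleGridML(fx$genotype, fx$panel), tolerance = 2e-4)
  # an asymmetric genotype too
  g <- MultilocusGenotype("asym", list(MHC = c("A", "A"),
    `1FWD` = c("A", "C"), `1REV` = c("CAG", "TGC"), `4FWD` = c("C", "C"),
    `4REV` = c("A", "C")), mtdna = "A")
  expect_equal(mlHybridIndex(g, fx$panel)$h, oracleGridML(g, fx$panel),
    tolerance = 2e-4)
})

test_that("ML orientation B1 mirrors the estimate and interval", {
  a <- mlHybridIndex(fx$genotype, fx$panel)
  b <- mlHybridIndex(fx$genotype, fx$panel, orientation = "B1")
  expect_equal(b$h, 1 - a$h, tolerance = 1e-9)
  expect_equal(b$ciLow, 1 - a$ciHigh, tolerance = 1e-9)
  expect_equal(b$ciHigh, 1 - a$ciLow, tolerance = 1e-9)
})
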