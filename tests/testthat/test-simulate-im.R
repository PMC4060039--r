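singleDemeSpec <- function(theta, n, lengthBp = 100, scalar = 1) {
  imModelSpec(theta, theta, theta, splitTime = 0,
    loci = data.frame(locus_id = "L1", length_bp = lengthBp,
      scalar = scalar, n0 = n, n1 = 0))
}

test_that("a single sampled lineage yields zero segregating sites", {
  spec <- singleDemeSpec(5, 1)
  sim <- coalescentIMSimulate(spec, seed = 4)
  aln <- sim$L1$pop0
  expect_equal(nHaplotypes(aln), 1L)
  expect_equal(length(alleleFrequencies(aln)[[1]]), 1L)
  expect_null(sim$L1$pop1)
})

test_that("same seed gives byte-identical output", {
  spec <- imModelSpec(3, 2, 4, splitTime = 1.5, m0to1 = 0.2, m1to0 = 0.05,
    loci = data.frame(locus_id = c("a", "b"), length_bp = c(80, 120),
      scalar = c(1, 0.25), n0 = c(4, 4), n1 = c(4, 4)))
  x <- coalescentIMSimulate(spec, seed = 123)
  y <- coalescentIMSimulate(spec, seed = 123)
  for (loc in names(x)) {
    expect_identical(as.character(x[[loc]]$pop0@haplotypes),
      as.character(y[[loc]]$pop0@haplotypes))
    expect_identical(as.character(x[[loc]]$pop1@haplotypes),
      as.character(y[[loc]]$pop1@haplotypes))
  }
})

test_that("padded alignments have the requested width", {
  spec <- singleDemeSpec(5, 8, lengthBp = 300)
  sim <- coalescentIMSimulate(spec, seed = 9)
  expect_equal(locusLength(sim$L1$pop0), 300L)
})

test_that("mean segregating sites follow the Watterson expectation", {
  # theta = 5, n = 10: E[S] = 5 * sum(1/1:9) = 14.14; modest replication
  # here, the full-scale run is in the acceptance suite
  spec <- singleDemeSpec(5, 10)
  set.seed(61)
  seeds <- sample.int(2^31 - 1, 1500)
  S <- vapply(seeds, function(sd)
    tajimasD(coalescentIMSimulate(spec, sd, pad = FALSE)$L1$pop0)$S,
    numeric(1))
  expect_lt(abs(mean(S) - 5 * sum(1 / 1:9)), 0.6)
})

test_that("neutral coalescent samples give Tajima's D centred near zero", {
  spec <- singleDemeSpec(5, 10)
  set.seed(62)
  seeds <- sample.int(2^31 - 1, 1000)
  D <- vapply(seeds, function(sd)
    tajimasD(coalescentIMSimulate(spec, sd, pad = FALSE)$L1$pop0)$tajimaD,
    numeric(1))
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.1)
})

test_that("inheritance scalar 0.25 quarters the pairwise diversity", {
  nuc <- singleDemeSpec(5, 10)
  mt <- singleDemeSpec(5, 10, scalar = 0.25)
  set.seed(63)
  seedsN <- sample.int(2^31 - 1, 300)
  seedsM <- sample.int(2^31 - 1, 300)
  piN <- vapply(seedsN, function(sd)
    tajimasD(coalescentIMSimulate(nuc, sd, pad = FALSE)$L1$pop0)$pi,
    numeric(1))
  piM <- vapply(seedsM, function(sd)
    tajimasD(coalescentIMSimulate(mt, sd, pad = FALSE)$L1$pop0)$pi,
    numeric(1))
  expect_lt(abs(mean(piN) - 5), 1)
  expect_lt(abs(mean(piM) - 1.25), 0.3)
  expect_lt(abs(mean(piM) / mean(piN) - 0.25), 0.08)
})

test_that("no recombination: four-gamete Rm is zero at every locus", {
  spec <- imModelSpec(4, 4, 4, splitTime = 10, m0to1 = 0.1, m1to0 = 0,
    loci = data.frame(locus_id = sprintf("L%d", 1:8), length_bp = 150,
      scalar = 1, n0 = 6, n1 = 6))
  sim <- coalescentIMSimulate(spec, seed = 64)
  for (loc in names(sim)) {
    pooled <- LocusAlignment(loc,
      c(as.character(sim[[loc]]$pop0@haplotypes),
        as.character(sim[[loc]]$pop1@haplotypes)))
    expect_identical(fourGameteRm(pooled), 0L)
  }
})

test_that("old split without migration separates demes", {
  spec <- imModelSpec(2, 2, 2, splitTime = 25, m0to1 = 0, m1to0 = 0,
    loci = data.frame(locus_id = sprintf("L%d", 1:6), length_bp = 400,
      scalar = 1, n0 = 5, n1 = 5))
  sim <- coalescentIMSimulate(spec, seed = 65)
  between <- numeric(0); within <- numeric(0)
  for (loc in names(sim)) {
    h0 <- haplotypeMatrix(sim[[loc]]$pop0)
    h1 <- haplotypeMatrix(sim[[loc]]$pop1)
    for (a in 1:5) for (b in 1:5)
      between <- c(between, sum(h0[a, ] != h1[b, ]))
    for (a in 1:4) for (b in (a + 1):5) {
      within <- c(within, sum(h0[a, ] != h0[b, ]),
        sum(h1[a, ] != h1[b, ]))
    }
  }
  expect_gt(mean(between), mean(within))
})

test_that("spec validation rejects bad configurations", {
  expect_error(imModelSpec(-1, 1, 1, 0, loci = data.frame(
    locus_id = "x", length_bp = 10, scalar = 1, n0 = 2, n1 = 0)), ">= 0")
  expect_error(imModelSpec(1, 1, 1, 0, loci = data.frame(
    locus_id = "x", length_bp = 10, scalar = 0, n0 = 2, n1 = 0)), "scalar")
  expect_error(imModelSpec(1, 1, 1, 0, loci = data.frame(
    locus_id = "x", length_bp = 10, scalar = 1, n0 = 0, n1 = 0)),
    "at least one sample")
})
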