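---
title: "Classifying F1 hybrids and testing siring asymmetry with diagnostic markers"
author: "hybridcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying F1 hybrids and testing siring asymmetry with diagnostic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcross)
```

## The problem

When two closely related species breed in sympatry, occasional hybrids
appear. Two questions follow immediately. First, are the hybrids
first-generation (F1) crosses or later-generation backcrosses? Second, is
there a *siring asymmetry* — does one species' males father most or all of
the hybrids? The second question only makes sense for F1s: once backcrossing
begins, the maternal signal is scrambled by random mating.

Both questions can be answered with a small panel of **diagnostic nuclear
markers** (sites whose alleles distinguish the parental species at high
probability) plus one maternally inherited mitochondrial marker. The worked
system in this package is the Black-footed × Laysan Albatross pair
(*Phoebastria nigripes* × *P. immutabilis*), but every function is written
for an arbitrary two-species system.

`hybridcross` implements the full chain: diagnostic-site discovery from
parental haplotype panels, per-locus screens (Tajima's D, the four-gamete
recombination test), two hybrid indices, exact cross-class genotype
probabilities with strict maternal mtDNA inheritance, an exact binomial test
of siring asymmetry, AIC ranking of isolation-with-migration (IM) model
fits, and seeded simulators (Mendelian crosses; a two-population IM
coalescent) that generate every input the pipeline consumes.

## Diagnostic markers

Given per-locus haplotype alignments for each species,
`findDiagnosticMarkers()` flags a site when species A's majority allele has
frequency at least `threshold` (default 0.90) within A and at most
`1 - threshold` in B, and symmetrically for B. The two-sided rule means a
single allele read at a qualifying site identifies the species of origin
with at least 90% probability even when one allele is shared at low
frequency. Qualifying sites within a locus are collapsed into a single
haplotype-block marker (alleles are the concatenated site states, e.g.
`CAG`/`TGC`); unlinked markers are assumed independent everywhere
downstream, so linked sites must never be split across markers.

```{r}
panels <- buildAlbatrossAlignments()
findDiagnosticMarkers(panels$panelA, panels$panelB)[,
  c("locus_id", "allele_A", "allele_B", "freq_A_in_A", "freq_B_in_B")]
```

The canonical five-marker albatross panel (four fixed differences, one
marker whose species-B allele segregates at 0.10 in species A) is built by
`buildAlbatrossFixture()`; `buildAlbatrossAlignments()` provides synthetic
haplotype alignments realizing exactly those frequencies (20 haplotypes per
species, 18:2 at the shared site), so the discovery step can be exercised
end to end.

## Hybrid indices

Two estimators of the proportion of an individual's genome derived from
species A are provided; both are oriented so **pure species A scores 1 and
pure species B scores 0**, and both accept `orientation = "B1"` to flip the
scale, since either convention appears in the literature and silent
orientation mistakes are a classic source of confusion.

**Diagnostic index** (`diagnosticIndex()`): the mean over all allele copies
of the equal-prior posterior that the copy originated in species A,
\(P(A \mid x) = f_A(x) / (f_A(x) + f_B(x))\). With fixed differences each
heterozygous marker contributes exactly 0.5. A shared low-frequency allele
pulls heterozygotes slightly off 0.5: on the canonical panel a fully
heterozygous F1 scores 0.5091 (0.51 at two decimals), not 0.50, because the
species-B allele at the shared marker retains a 0.1/1.1 posterior of A
origin. This estimator uses only diagnostic markers and needs no
optimization; it is the right summary when the panel is small and nearly
fixed.

**Maximum-likelihood index** (`mlHybridIndex()`): maximizes
\(L(h) = \prod_m P(g_m \mid h)\) with
\(P(\{a,b\} \mid h) = q(a)\,q(b)\,(2\ \mathrm{if}\ a \neq b)\) and
\(q(x) = h f_A(x) + (1-h) f_B(x)\), over all markers with panel
frequencies, diagnostic or not. The 95% interval is the
profile-likelihood set \(\{h : \log L(h) \ge \log L(\hat h) - 1.92\}\)
(the \(\chi^2_1\) half-width) intersected with \([0,1]\) — a standard
choice; nothing in the data motivates anything more elaborate at five to
nine markers. Maximization is golden-section/parabolic (`stats::optimize`)
at tolerance 1e-6 with explicit boundary comparison; ties resolve to the
boundary. The test suite checks the optimizer against a dense grid search
(step 1e-4) of the same likelihood.

```{r}
fx <- buildAlbatrossFixture()
diagnosticIndex(fx$genotype, fx$panel)
mlHybridIndex(fx$genotype, fx$panel)[c("h", "ciLow", "ciHigh")]
```

## Exact cross-class genotype probabilities

`genotypeProbGivenCross()` computes, by exact gamete enumeration, the
probability that an offspring of a given pedigree class carries an observed
multilocus genotype *and* mtDNA lineage. The nine classes
(`crossClasses()`) are the two pure classes, both reciprocal F1s, the four
BC1 combinations (F1 parent's sex × recurrent species), and F2.

Three modelling choices matter:

* **Pure parents are population draws.** A pure parent's genotype is drawn
  from its species' panel frequencies (Hardy–Weinberg), so its transmitted
  gamete is marginally a draw from the allele frequencies. Shared
  polymorphism therefore propagates into backcross probabilities.
* **The F1 parent is unconditioned.** Inside BC and F2 classes the F1
  parent is generated as a fresh F1 (one gamete from each species), *not*
  conditioned on the genotype observed in the focal hybrids. Its gamete
  distribution at each marker is the equal mixture of the two species'
  frequencies. On the canonical panel this yields backcross probabilities
  of 0.45 × 0.5⁴ = 0.028125 (F1♀ × B♂) and 0.54 × 0.5⁴ = 0.03375 (either
  backcross to A). Conditioning on the observed F1 genotype would instead
  give 0.03125 for every class and would conflate the sampled hybrids with
  their hypothetical parent.
* **mtDNA is strictly maternal.** Each class fixes the offspring's mtDNA
  lineage through the dam; the mtDNA factor is 0 or 1. A genotype carrying
  species-A mtDNA is impossible under any cross with a species-B dam. The
  maternal species of the F1 parent inside BC/F2 classes defaults to A
  (`f1Maternal = "A"`) and is configurable.

`classifyHybrid()` renormalizes prior-weighted class probabilities into
posteriors (uniform prior by default) and reports both; a genotype with
zero probability under every candidate class returns an explicit
`inconsistent` attribute rather than dividing by zero.

```{r}
genotypeProbGivenCross(fx$genotype, "F1_motherA", fx$panel)
classifyHybrid(fx$genotype, fx$panel,
  c("F1_motherA", "BC_F1female_x_Bmale", "BC_F1female_x_Amale",
    "BC_F1male_x_Afemale"))
```

## Siring asymmetry and model ranking

If all F1s carry species-A mtDNA, every hybrid had a species-A mother (and
a species-B father). `exactBinomialTwoSided(k, n, p0 = 0.5)` tests this
with the doubled-smaller-tail rule
\(p = \min(1,\, 2\min(P(X \le k), P(X \ge k)))\) from exact pmf summation;
six of six gives \(2 \times 0.5^6 = 0.03125\). The doubling rule is stated
explicitly because two-sided exact binomial p-values are
convention-dependent; at \(p_0 = 0.5\) it coincides with the
minimum-likelihood convention.

Long-term gene-flow direction is assessed by ranking IM model fits.
`aicRank()` consumes a table of (label, maximized log-likelihood, parameter
count) — never re-running the MCMC that produced it — and computes
\(AIC = 2k - 2\log L\), ΔAIC, and Akaike weights
\(w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}\), renormalized over exactly
the supplied model set (weights are only comparable within one set).
`cumulativeWeight()` sums the top-n weights; `demographicRescale()` converts
mutation-scaled \(\theta\) and \(m\) into \(N = \theta/(4 u_g g)\) and
\(2Nm = \theta m / 2\) given a per-locus yearly mutation rate, a generation
time, and an inheritance scalar \(g\) (1.0 autosomal, 0.25 mtDNA — mtDNA is
haploid and uniparental, so it has a quarter of the autosomal effective
copy number). A 25-model fit table for the albatross system ships in
`inst/extdata/` and loads with `readModelFits()`.

Neutrality and no-recombination assumptions behind IM fitting are screened
per locus with `tajimasD()` (undefined, reported `NA`, exactly when the
locus is invariant; requires n ≥ 3, and at n = 3 the 1989 variance
coefficients vanish, so interpret only n ≥ 4) and `fourGameteRm()`
(Hudson–Kaplan minimum recombination count: the maximum number of disjoint
site intervals whose endpoints show all four gametes).

## The synthetic-data generators

The package generates its own study inputs; no field data are required.

**Mendelian cross simulator** (`simulateCrossOffspring()`,
`simulateParentalPanel()`). Draws parents per pedigree class from panel
frequencies (F1 parents unconditioned, mirroring the exact calculation),
transmits one allele per marker with probability ½, treats markers as
unlinked, and propagates mtDNA strictly maternally. It shares no code with
`genotypeProbGivenCross()`; the convergence of Monte-Carlo match
frequencies to the exact probabilities is the primary cross-validation of
both, and runs at n = 200,000 (F1) and n = 500,000 (backcross) in the
acceptance suite.

**IM coalescent simulator** (`imModelSpec()`, `coalescentIMSimulate()`).
A structured-coalescent simulator for two populations that split from an
ancestor at `splitTime` with ongoing asymmetric migration. Parameters are
mutation-scaled (\(\theta = 4Nu g\) per locus, migration per lineage,
times in mutation units): looking backward, lineages in deme *i* coalesce
at rate \(k_i(k_i-1)/(\theta_i g)\), migrate at their per-lineage rate, and
merge into the ancestral deme at the split. Mutations fall on the genealogy
as a Poisson process at rate 1 per lineage per unit time under the
**infinite-sites** model, so a single deme has expected pairwise diversity
\(\theta g\) and expected segregating sites
\(\theta g \sum_{i<n} 1/i\) — closed forms the tests verify (θ = 5, n = 10,
10,000 replicates ⇒ E[S] = 14.14 ± 0.3; scalar 0.25 gives ≈ ¼ the nuclear
diversity). Infinite sites was chosen over a finite-sites HKY overlay
precisely because it admits these exact expectations and cannot produce
back-mutations; the cost is no transition/transversion structure and
strictly biallelic sites (written as A/T in FASTA output). There is no
intra-locus recombination, so every locus has one genealogy and
`fourGameteRm()` is 0 by construction — matching the screened loci the
pipeline expects. The simulation sizes above (10⁴ replicates at n = 10 for
means; a few hundred replicates for diversity ratios) were chosen as the
smallest scales at which the Monte-Carlo error is comfortably inside the
asserted bounds.

What the generators deliberately do *not* emulate: genotyping error and
allelic dropout, linkage between nuclear markers, selection, population
structure within species, more than two descendant populations, and
finite-sites homoplasy. Passing tests therefore demonstrate correctness of
the probability model and estimators under the stated assumptions, not
robustness of the pipeline to artifacts of real sequence data.

## Numerical and design notes

* **Missing data.** Haplotypes with `N`/gap at a site are dropped from that
  site's denominator in every frequency and diversity computation — the
  smallest-assumption treatment.
* **Boundary frequencies.** The diagnostic threshold comparisons carry a
  1e-12 guard so an exact 0.10 shared-allele frequency is not rejected by
  floating-point representation of `1 - 0.90`.
* **Unordered genotypes.** Allele pairs are stored lexicographically;
  `a/b` and `b/a` in genotype tables parse identically, and writers emit
  deterministic output.
* **HPD-style intervals.** `hpdInterval()` returns the shortest contiguous
  window covering `ceiling(mass * n)` sorted points; width ties break to
  the smallest lower endpoint, making the result deterministic.
* **Determinism.** Every stochastic function takes an explicit seed and is
  byte-reproducible under it.
* **Orientation.** The A = 1 orientation is the package default because the
  diagnostic index is most often read as "proportion of ancestry from the
  species whose mothers bore the hybrids"; `orientation = "B1"` serves the
  opposite convention. Downstream probabilities are orientation-free.

## Limitations

The class set stops at F2/BC1: later-generation hybrids (F3, BC2, …) are
not modelled, and with five markers they are barely distinguishable anyway.
The ML index assumes independent markers and ignores genotyping
uncertainty. The IM simulator is a generative tool for testing and power
exploration — it does not fit the IM model to data, and `aicRank()` assumes
the supplied log-likelihoods are comparable (same data, nested or
non-nested models fitted by the same machinery).
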