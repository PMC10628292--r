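test_that("computeBaf returns alt/(ref+alt), NA at zero depth, errors on negatives", {
  expect_equal(computeBaf(10, 10), 0.5)
  expect_equal(computeBaf(0, 7), 1.0)
  expect_equal(computeBaf(67, 133), 0.665)
  expect_true(is.na(computeBaf(0, 0)))
  expect_equal(computeBaf(c(10, 0), c(10, 0)), c(0.5, NA))
  expect_error(computeBaf(-1, 5), "non-negative")
})

test_that("orientGainedAlleles keeps heterozygous informative SNPs and orients to the tumor majority allele", {
  sites <- snpSites("chr11", c(100, 200, 300, 400, 500),
                    refNT = c(10, 10, 10, 1, 10),
                    altNT = c(10, 11, 9, 19, 10),
                    refT  = c(2, 10, 18, 2, 10),
                    altT  = c(18, 10, 2, 18, 0))
  ## site 2: tumor BAF exactly 0.5 -> dropped; site 4: homozygous-ish NT
  ## (BAF 0.95) -> dropped; sites 1, 3, 5 pass het filter; site 5 tumor BAF 0
  locus <- testLocus()
  oriented <- orientGainedAlleles(sites, locus)
  expect_equal(GenomicRanges::start(oriented), c(100, 300, 500))
  expect_equal(S4Vectors::mcols(oriented)$gainedIsAlt, c(TRUE, FALSE, FALSE))

  ## depth filter: NT depth below minDepth drops the site
  low <- snpSites("chr11", 600, refNT = 3, altNT = 3, refT = 1, altT = 9)
  expect_warning(out <- orientGainedAlleles(low, locus, minDepth = 8),
                 "no informative SNPs")
  expect_length(out, 0)

  ## an explicit germline reference overrides the non-tumor filter
  oriented2 <- orientGainedAlleles(sites[4], locus,
                                   germlineBaf = 0.5, germlineDepth = 30)
  expect_length(oriented2, 1)

  expect_error(orientGainedAlleles(sites, locus, hetLow = 0.6),
               "thresholds")
})

test_that("estimateGaf is the median non-tumor BAF of the gained allele", {
  expect_equal(estimateGaf(makeOrientedSites(c(0.6, 0.7, 0.8), 10)), 0.7)
  expect_equal(estimateGaf(makeOrientedSites(c(0.5, 0.5), 10)), 0.5)
  ## even count: midpoint of the middle pair
  expect_equal(estimateGaf(makeOrientedSites(c(0.66, 0.67, 0.68, 0.64), 100)),
               0.665)
  ## orientation matters: gained allele on the reference side uses 1 - BAF
  sites <- makeOrientedSites(c(0.3, 0.3), 10)
  S4Vectors::mcols(sites)$gainedIsAlt <- c(FALSE, FALSE)
  expect_equal(estimateGaf(sites), 0.7)
  expect_error(estimateGaf(makeOrientedSites(numeric(0))), "zero oriented")
})

test_that("mosaicFraction inverts the allelic-dosage mixture for both alteration classes", {
  cnloh <- testLocus("cn_LOH")
  patdup <- testLocus("paternal_dup")
  expect_equal(mosaicFraction(0.5, cnloh), 0)
  expect_equal(mosaicFraction(0.665, cnloh), 33)
  expect_equal(mosaicFraction(12 / 22, patdup), 20, tolerance = 1e-12)
  expect_equal(mosaicFractionCnLoh(0.5), 0)
  expect_equal(mosaicFractionCnLoh(1.0), 100)
  expect_equal(mosaicFractionCnLoh(0.79), 58, tolerance = 1e-12)
  ## degenerate denominator for a fully duplicated sample
  expect_error(mosaicFraction(1, patdup), "denominator")
  ## below-0.5 GAF clamps to 0 with the raw value kept
  expect_warning(f <- mosaicFractionCnLoh(0.49), "clamped")
  expect_equal(as.numeric(f), 0)
  expect_equal(attr(f, "raw"), -2, tolerance = 1e-9)
})

test_that("the general mixture inversion reduces to the cn-LOH closed form and is exact for both classes", {
  gaf <- seq(0, 1, by = 0.01)
  cnloh <- testLocus("cn_LOH")
  expect_equal(suppressWarnings(as.numeric(mosaicFraction(gaf, cnloh))),
               suppressWarnings(as.numeric(mosaicFractionCnLoh(gaf))),
               tolerance = 1e-12)
  ## mixture-inversion identities: fraction(dosage(rho)) == 100 rho
  rho <- seq(0, 1, by = 0.001)
  expect_equal(as.numeric(mosaicFraction(gainedDosage(rho, "cn_LOH"), cnloh)),
               100 * rho, tolerance = 1e-9)
  rhoD <- rho[rho < 1]  # rho = 1 is the degenerate paternal-dup denominator
  patdup <- testLocus("paternal_dup")
  expect_equal(as.numeric(mosaicFraction(gainedDosage(rhoD, "paternal_dup"),
                                         patdup)),
               100 * rhoD, tolerance = 1e-9)
  ## monotone in GAF on [0.5, 1]
  up <- seq(0.5, 1, by = 0.005)
  expect_true(all(diff(as.numeric(mosaicFraction(up, cnloh))) >= 0))
  expect_true(all(diff(suppressWarnings(
    as.numeric(mosaicFraction(head(up, -1), patdup)))) >= 0))
})

test_that("detectMosaicism aggregates reads into one exact binomial tail test", {
  ## 60 SNPs x 20 reads = 1200 reads, 600 gained: balanced, not detected
  half <- makeOrientedSites(rep(0.5, 60), depthNT = 20)
  est <- detectMosaicism(half, testLocus())
  expect_s4_class(est, "MosaicEstimate")
  ## frozen from the normal-approximated exact tail:
  ## P(X >= 600) = 1/2 + P(X = 600)/2 ~ 0.5115
  expect_equal(pValue(est), 0.5115, tolerance = 1e-3)
  expect_false(isDetected(est))
  expect_equal(fractionPct(est), 0)

  ## 660/1200 gained: strongly detected
  skew <- makeOrientedSites(rep(0.55, 60), depthNT = 20)
  est2 <- detectMosaicism(skew, testLocus())
  expect_lt(pValue(est2), 0.001)
  expect_true(isDetected(est2))

  ## saturated signal: all reads gained at depth 20
  sat <- makeOrientedSites(c(1, 1), depthNT = 10)
  est3 <- suppressWarnings(detectMosaicism(sat, testLocus()))
  expect_equal(fractionPct(est3), 100)
  expect_true(isDetected(est3))
  expect_equal(nSnps(est3), 2L)

  expect_error(detectMosaicism(makeOrientedSites(numeric(0)), testLocus()),
               "zero oriented")
})

test_that("aggregated and per-SNP p-values equal the explicit binomial tail sum at small n", {
  for (seed in 1:5) {
    set.seed(seed)
    nSites <- sample(2:5, 1)
    depth <- sample(4:10, nSites, replace = TRUE)
    gained <- vapply(depth, function(d) sample(0:d, 1), integer(1))
    sites <- makeOrientedSites(gained / depth, depthNT = depth,
                               gainedReadsNT = gained)
    est <- suppressWarnings(detectMosaicism(sites, testLocus()))
    expect_equal(pValue(est), oracleBinomTailHalf(sum(gained), sum(depth)),
                 tolerance = 1e-12)
    expect_equal(est@perSnp$pValue,
                 mapply(oracleBinomTailHalf, gained, depth),
                 tolerance = 1e-12)
  }
})

test_that("areaFraction converts annotated section areas into a percentage", {
  expect_equal(fractionPct(areaFraction(0, 50)), 0)
  expect_equal(fractionPct(areaFraction(50, 50)), 100)
  expect_equal(fractionPct(areaFraction(14, 100)), 14)
  expect_equal(estimateMethod(areaFraction(14, 100)), "area")
  expect_error(areaFraction(60, 50), "mosaicArea")
  expect_error(areaFraction(1, 0), "positive")
})
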