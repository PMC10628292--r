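test_that("icMeans averages non-excluded probes per imprinting center", {
  p <- mlpaProbes(paste0("a", 1:6), rep(c("IC1", "IC2"), c(3, 3)),
                  c(0.6, 0.6, 0.6, 0.4, 0.5, 0.6))
  expect_equal(icMeans(p), c(ic1 = 0.6, ic2 = 0.5))

  ## the default-excluded IC1 probe does not contribute
  p2 <- mlpaProbes(c(DEFAULT_EXCLUDED_PROBES, "b1", "b2", "b3", "c1"),
                   c("IC1", "IC1", "IC1", "IC1", "IC2"),
                   c(0.1, 0.5, 0.7, 0.9, 0.5))
  expect_equal(icMeans(p2)[["ic1"]], 0.7)

  p3 <- mlpaProbes(c("IC2_p1", "IC2_p2", "IC2_p3", "IC2_p4", "x"),
                   c(rep("IC2", 4), "IC1"),
                   c(0.4, 0.5, 0.5, 0.6, 0.5))
  expect_equal(icMeans(p3)[["ic2"]], 0.5)

  allExcluded <- mlpaProbes(c(DEFAULT_EXCLUDED_PROBES, "c1"),
                            c("IC1", "IC2"), c(0.5, 0.5))
  expect_error(icMeans(allExcluded), "IC1")
})

test_that("icRatio and the methylation mosaic fraction follow the imprinting dosage model", {
  expect_equal(icRatio(0.6, 0.6), 1)
  expect_equal(icRatio(0.75, 0.5), 1.5)
  expect_equal(icRatio(0.5, 1.0), 0.5)
  expect_error(icRatio(0.5, 0), "positive")

  expect_equal(as.numeric(mosaicFractionMethylation(0.6, 0.6)), 0)
  expect_equal(as.numeric(mosaicFractionMethylation(0.625, 0.375)), 25)
  expect_equal(as.numeric(mosaicFractionMethylation(1.0, 0.0)), 100)
  expect_error(mosaicFractionMethylation(0, 0), "positive")
  expect_warning(f <- mosaicFractionMethylation(0.4, 0.6), "clamped")
  expect_equal(as.numeric(f), 0)
  expect_lt(attr(f, "raw"), 0)
})

test_that("the methylation fraction recovers rho exactly under the symmetric mixture", {
  rho <- seq(0, 1, by = 0.01)
  ic1 <- 0.5 * (1 + rho)
  ic2 <- 0.5 * (1 - rho)
  got <- vapply(seq_along(rho), function(i)
    as.numeric(mosaicFractionMethylation(ic1[i], ic2[i])), numeric(1))
  expect_equal(got, 100 * rho, tolerance = 1e-12)
  ## ratio 1 <=> fraction 0
  expect_equal(icRatio(0.6, 0.6), 1)
  expect_equal(as.numeric(mosaicFractionMethylation(0.6, 0.6)), 0)
  expect_gt(as.numeric(mosaicFractionMethylation(0.61, 0.6)), 0)
})

.cohortMatrix <- function(nSamples, altered = integer(0), delta = 0.4,
                          base = 0.5, sd = 0.02, seed = 1) {
  set.seed(seed)
  probes <- c(paste0("IC1_p", 1:3), paste0("IC2_p", 1:4))
  target <- rep(c("IC1", "IC2"), c(3, 4))
  m <- matrix(stats::rnorm(length(probes) * nSamples, base, sd),
              nrow = length(probes),
              dimnames = list(probes, sprintf("S%02d", seq_len(nSamples))))
  m[1:3, altered] <- m[1:3, altered] + delta        # GOM IC1
  m[4:7, altered] <- m[4:7, altered] - delta        # LOM IC2
  list(values = pmin(pmax(m, 0), 1), target = target)
}

test_that("classifyEpimutation flags samples by the 2/3 and 2/4 probe rules", {
  ch <- .cohortMatrix(10, altered = 7)
  calls <- classifyEpimutation(ch$values, ch$target)
  expect_equal(calls$gom_ic1, seq_len(10) == 7)
  expect_equal(calls$lom_ic2, seq_len(10) == 7)

  ## one of three IC1 probes above threshold is not enough; altered samples
  ## 1-2 anchor the probe thresholds around 0.7
  ch2 <- .cohortMatrix(10, altered = 1:2)
  ch2$values["IC1_p1", 3] <- 0.95
  calls2 <- classifyEpimutation(ch2$values, ch2$target)
  expect_false(calls2$gom_ic1[3])

  ## two of four IC2 probes in the loss direction suffice
  ch3 <- .cohortMatrix(10, altered = 1:2)
  ch3$values[c("IC2_p1", "IC2_p2"), 5] <- 0.02
  calls3 <- classifyEpimutation(ch3$values, ch3$target)
  expect_true(calls3$lom_ic2[5])
  expect_false(calls3$gom_ic1[5])

  ## degenerate cohort: all identical values -> warning, all-negative calls
  flat <- matrix(0.5, nrow = 7, ncol = 4,
                 dimnames = list(rownames(ch$values), NULL))
  expect_warning(calls4 <- classifyEpimutation(flat, ch$target),
                 "degenerate")
  expect_false(any(calls4$gom_ic1) || any(calls4$lom_ic2))

  expect_error(classifyEpimutation(ch$values[1:4, ], ch$target[1:4]),
               "IC2")
  expect_error(classifyEpimutation(ch$values[, 1, drop = FALSE], ch$target),
               "2 samples")
})

test_that("per-probe k-means thresholds agree with the exhaustive 2-partition oracle", {
  for (seed in 1:10) {
    ch <- .cohortMatrix(sample(4:12, 1), altered = 1:2, delta = 0.35,
                        sd = 0.04, seed = seed)
    thrImpl <- apply(ch$values, 1, mosaic11p:::.kmeansThreshold1d)
    thrOracle <- apply(ch$values, 1, oracleKmeans2Threshold)
    expect_equal(thrImpl, thrOracle, tolerance = 1e-9)
  }
})

test_that("rrbsRegionMethylation pools counts over in-region CpGs", {
  region <- icRegions()["IC1"]
  pos <- GenomicRanges::start(region) + c(10, 20, 30)
  cpgs <- rrbsCpgs("chr11", pos, methCount = c(5, 3, 1),
                   unmethCount = c(5, 1, 3))
  expect_equal(rrbsRegionMethylation(cpgs[1], region), 0.5)
  ## pooled-count ratio (3+1)/(3+1+1+3), not the mean of per-CpG ratios
  expect_equal(rrbsRegionMethylation(cpgs[2:3], region), 0.5)
  full <- rrbsCpgs("chr11", pos, methCount = c(4, 4, 4),
                   unmethCount = c(0, 0, 0))
  expect_equal(rrbsRegionMethylation(full, region), 1.0)

  ## invariant to CpG order and to splitting a CpG across duplicate records
  perm <- cpgs[c(3, 1, 2)]
  expect_equal(rrbsRegionMethylation(perm, region),
               rrbsRegionMethylation(cpgs, region))
  split2 <- rrbsCpgs("chr11", c(pos, pos[2]), methCount = c(5, 1, 1, 2),
                     unmethCount = c(5, 0, 3, 1))
  expect_equal(rrbsRegionMethylation(split2, region),
               rrbsRegionMethylation(cpgs, region))

  ## exclusion list and empty-region behavior
  expect_equal(rrbsRegionMethylation(cpgs, region, excludeCpgs = cpgs[2:3]),
               0.5)
  outside <- rrbsCpgs("chr11", 1, 5, 5)
  expect_true(is.na(rrbsRegionMethylation(outside, region)))
})

test_that("classifyMosaicByRatio flags strict outliers beyond k SDs of the normal cohort", {
  set.seed(1)
  normals <- stats::rnorm(50, 1, 0.02)
  expect_false(classifyMosaicByRatio(1.0, normals))
  expect_true(classifyMosaicByRatio(1.5, normals))
  expect_true(classifyMosaicByRatio(0.5, normals))
  ## exactly at mean + 3 SD: strict inequality, not flagged
  m <- mean(normals); s <- stats::sd(normals)
  expect_false(classifyMosaicByRatio(m + 3 * s, normals))
  expect_error(classifyMosaicByRatio(1, rep(1, 5)), "variance")
})

test_that("summarizeMethylation assembles a MethylationSummary", {
  p <- mlpaProbes(paste0("a", 1:7), rep(c("IC1", "IC2"), c(3, 4)),
                  c(rep(0.625, 3), rep(0.375, 4)))
  s <- summarizeMethylation(p, sampleId = "s1")
  expect_s4_class(s, "MethylationSummary")
  expect_equal(icMeanValues(s), c(ic1 = 0.625, ic2 = 0.375))
  expect_equal(icRatioValue(s), 0.625 / 0.375)
  expect_equal(s@fractionPct, 25)
})
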