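## Independent oracles, kept deliberately naive.

## Exact upper binomial tail P(X >= k | n, p = 1/2) as an explicit sum over
## binomial coefficients (usable for n <= ~50).
oracleBinomTailHalf <- function(k, n) {
  if (k <= 0) return(1)
  sum(choose(n, k:n)) / 2^n
}

## Exhaustive optimal 2-partition of 1-D data by within-cluster sum of
## squares: every one of the 2^n - 2 non-trivial subset assignments is
## scored (feasible for n <= ~14), so the search is not restricted to
## contiguous splits. Returns the midpoint of the two cluster means, or NA
## when the data do not separate.
oracleKmeans2Threshold <- function(x) {
  n <- length(x)
  if (diff(range(x)) < 1e-12) return(NA_real_)
  best <- Inf; thr <- NA_real_
  for (mask in seq_len(2^n - 2)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    a <- x[inA]; b <- x[!inA]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best - 1e-12) {
      best <- ss
      thr <- (mean(a) + mean(b)) / 2
    }
  }
  thr
}

## Literal transcription of the per-cell calling rule.
oracleCallCell <- function(pat, mat, minReads = 8, lohBaf = 0.85,
                           refBaf = 0.60) {
  total <- pat + mat
  if (total < minReads) return("unknown")
  baf <- pat / total
  if (baf >= lohBaf) return("cn_LOH")
  if (baf <= refBaf) return("no_cnLOH")
  "unknown"
}

## Build an oriented SNP-site GRanges directly from non-tumor gained-allele
## BAFs (bypassing the filters), for unit tests of GAF/detection arithmetic.
makeOrientedSites <- function(gainedBafNT, depthNT = 1000,
                              gainedReadsNT = NULL) {
  n <- length(gainedBafNT)
  altNT <- if (is.null(gainedReadsNT)) round(gainedBafNT * depthNT) else
    gainedReadsNT
  depthNT <- rep_len(depthNT, n)
  sites <- snpSites(rep("chr11", n), seq_len(n) * 100,
                    refNT = depthNT - altNT, altNT = altNT,
                    refT = rep(1, n), altT = rep(9, n))
  S4Vectors::mcols(sites)$gainedIsAlt <- rep(TRUE, n)
  sites
}

testLocus <- function(alteration = "cn_LOH")
  MosaicLocus("chr11", 1, 2800000, alteration)
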