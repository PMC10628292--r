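#' B-allele frequency from allele read counts
#'
#' @param ref,alt Non-negative read counts supporting the reference and
#'   alternate allele. Vectorized.
#' @return alt/(ref+alt); `NA` where the total depth is zero.
#' @examples
#' computeBaf(10, 10)   # 0.5
#' computeBaf(67, 133)  # 0.665
#' @export
computeBaf <- function(ref, alt) {
  if (any(is.na(ref)) || any(is.na(alt)) || any(ref < 0) || any(alt < 0))
    stop("read counts must be non-negative")
  depth <- ref + alt
  ifelse(depth == 0, NA_real_, alt / depth)
}

#' Select informative SNPs and orient them to the tumor-gained allele
#'
#' Keeps SNPs inside the locus that look germline-heterozygous in the
#' designated germline reference (BAF within the heterozygosity window at
#' sufficient depth) and whose tumor BAF is strictly off 0.5, then records
#' which allele is gained in the tumor: `gainedIsAlt` is `TRUE` when the
#' tumor BAF exceeds 0.5. Sites with an undefined tumor BAF or a tumor BAF of
#' exactly 0.5 carry no orientation and are dropped.
#'
#' When no separate germline sample is available the non-tumor sample itself
#' serves as the heterozygosity reference; at high mosaic fractions its BAF is
#' shifted, which the detection step flags (see [detectMosaicism()]).
#'
#' @param sites SNP-site `GRanges` from [snpSites()].
#' @param locus A [MosaicLocus-class]; only overlapping SNPs are used.
#' @param hetLow,hetHigh Heterozygosity window on the germline BAF
#'   (defaults 0.2 and 0.8); must satisfy `0 < hetLow < 0.5 < hetHigh < 1`.
#' @param minDepth Minimum germline depth for the heterozygosity call
#'   (default 8).
#' @param germlineBaf Optional per-site BAF from a dedicated germline sample
#'   (e.g. blood) with `germlineDepth`; by default the non-tumor sample is
#'   used.
#' @param germlineDepth Optional per-site depth matching `germlineBaf`.
#' @return The oriented subset of `sites` with a logical metadata column
#'   `gainedIsAlt`. Empty output (no informative SNPs) raises a warning.
#' @export
orientGainedAlleles <- function(sites, locus, hetLow = 0.2, hetHigh = 0.8,
                                minDepth = 8, germlineBaf = NULL,
                                germlineDepth = NULL) {
  .assertSnpSites(sites)
  stopifnot(is(locus, "MosaicLocus"))
  if (!(hetLow > 0 && hetLow < 0.5 && hetHigh > 0.5 && hetHigh < 1))
    stop("thresholds must satisfy 0 < hetLow < 0.5 < hetHigh < 1")

  usedNTAsGermline <- is.null(germlineBaf)
  if (usedNTAsGermline) {
    germlineBaf <- mcols(sites)$bafNT
    germlineDepth <- mcols(sites)$refNT + mcols(sites)$altNT
  } else if (is.null(germlineDepth)) {
    stop("germlineDepth is required when germlineBaf is supplied")
  }

  inLocus <- IRanges::overlapsAny(sites, lociRegion(locus))
  het <- !is.na(germlineBaf) & germlineBaf >= hetLow & germlineBaf <= hetHigh &
    germlineDepth >= minDepth
  bafT <- mcols(sites)$bafT
  oriented <- !is.na(bafT) & bafT != 0.5

  keep <- inLocus & het & oriented
  out <- sites[keep]
  mcols(out)$gainedIsAlt <- mcols(out)$bafT > 0.5
  metadata(out)$germlineIsNonTumor <- usedNTAsGermline
  if (length(out) == 0L)
    warning("no informative SNPs after heterozygosity and orientation filters")
  out
}

## Non-tumor BAF of the gained allele, per oriented site.
.gainedBafNT <- function(oriented) {
  ifelse(mcols(oriented)$gainedIsAlt,
         mcols(oriented)$bafNT, 1 - mcols(oriented)$bafNT)
}

#' Median non-tumor BAF of the tumor-gained alleles (GAF)
#'
#' @param oriented Oriented SNP sites from [orientGainedAlleles()].
#' @return The median over sites of the non-tumor BAF of the gained allele;
#'   0.5 in balanced tissue, drifting towards 1 with the mosaic fraction.
#' @export
estimateGaf <- function(oriented) {
  if (length(oriented) == 0L)
    stop("cannot estimate GAF from zero oriented SNPs")
  if (is.null(mcols(oriented)$gainedIsAlt))
    stop("sites are not oriented; run orientGainedAlleles() first")
  stats::median(.gainedBafNT(oriented))
}

## Clamp a percentage into [0, 100]; keeps the raw value as an attribute and
## warns, because noise near a true fraction of 0 produces small negatives.
.clampPct <- function(x, context = "mosaic fraction") {
  raw <- x
  clamped <- pmin(pmax(x, 0), 100)
  if (any(clamped != raw)) {
    warning(sprintf("%s outside [0, 100] (raw value %s); clamped",
                    context, paste(signif(raw[clamped != raw], 4),
                                   collapse = ", ")))
    attr(clamped, "raw") <- raw
  }
  clamped
}

#' Mosaic cell fraction from the gained-allele frequency
#'
#' Inverts the allelic-dosage mixture: a tissue in which a fraction rho of
#' cells carries `nMaj` copies of the gained allele and `nMin` of the other
#' (remaining cells balanced, one copy each) shows a gained-allele frequency
#' `GAF = (1 + rho*(nMaj - 1)) / (2 + rho*(nMaj + nMin - 2))`, so
#' `rho = (2*GAF - 1) / (GAF*(2 - nMaj - nMin) + nMaj - 1)`.
#'
#' @param gaf Gained-allele frequency in [0, 1]; vectorized.
#' @param locus A [MosaicLocus-class] supplying the allele copy numbers.
#' @return Percentage of altered cells, clamped to [0, 100] (raw value kept
#'   in the `"raw"` attribute when clamping occurred).
#' @examples
#' loc <- MosaicLocus("chr11", 1, 2800000, "cn_LOH")
#' mosaicFraction(0.665, loc)  # 33
#' @export
mosaicFraction <- function(gaf, locus) {
  stopifnot(is(locus, "MosaicLocus"))
  if (any(gaf < 0 | gaf > 1)) stop("gaf must lie in [0, 1]")
  copies <- alleleCopies(locus)
  nMaj <- copies[["nMaj"]]; nMin <- copies[["nMin"]]
  denom <- gaf * (2 - nMaj - nMin) + nMaj - 1
  if (any(denom <= 0))
    stop("degenerate input: mixture denominator is not positive")
  .clampPct(100 * (2 * gaf - 1) / denom)
}

#' Mosaic cell fraction under copy-neutral LOH
#'
#' The cn-LOH special case of [mosaicFraction()]: with (nMaj, nMin) = (2, 0)
#' the mixture inversion reduces to `100 * (2*GAF - 1)`.
#'
#' @param gaf Gained-allele frequency in [0, 1]; vectorized.
#' @return Percentage of altered cells, clamped to [0, 100].
#' @examples
#' mosaicFractionCnLoh(0.79)  # 58
#' @export
mosaicFractionCnLoh <- function(gaf) {
  if (any(gaf < 0 | gaf > 1)) stop("gaf must lie in [0, 1]")
  .clampPct(100 * (2 * gaf - 1))
}

#' Detect and quantify mosaicism from oriented SNPs
#'
#' Aggregates gained-allele and total non-tumor reads over the oriented SNPs
#' and tests the gained-read proportion against 0.5 with a one-sided exact
#' binomial tail (`P(X >= k)` under `Binomial(n, 0.5)`). A single aggregated
#' test is used rather than combining per-SNP tests: it matches the summing
#' logic of the single-nucleus caller and maximizes power at low mosaic
#' fractions. Per-SNP tail p-values are retained in the result for
#' inspection.
#'
#' @param oriented Oriented SNP sites from [orientGainedAlleles()].
#' @param locus A [MosaicLocus-class].
#' @param alpha Detection level (default 0.05).
#' @return A [MosaicEstimate-class] with the GAF, mosaic fraction,
#'   aggregated p-value and per-SNP diagnostics. A warning is raised when the
#'   estimated fraction exceeds 40% and the non-tumor sample itself served as
#'   the heterozygosity reference, since high mosaicism shifts its BAF.
#' @export
detectMosaicism <- function(oriented, locus, alpha = 0.05) {
  if (length(oriented) == 0L)
    stop("cannot detect mosaicism from zero oriented SNPs")
  gainedReads <- ifelse(mcols(oriented)$gainedIsAlt,
                        mcols(oriented)$altNT, mcols(oriented)$refNT)
  totalReads <- mcols(oriented)$refNT + mcols(oriented)$altNT

  k <- sum(gainedReads); n <- sum(totalReads)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  perSnp <- S4Vectors::DataFrame(
    chrom = as.character(seqnames(oriented)),
    pos = start(oriented),
    gainedReads = gainedReads,
    totalReads = totalReads,
    gainedBafNT = .gainedBafNT(oriented),
    pValue = stats::pbinom(gainedReads - 1, totalReads, 0.5,
                           lower.tail = FALSE)
  )

  gaf <- estimateGaf(oriented)
  frac <- mosaicFraction(gaf, locus)
  if (frac > 40 && isTRUE(metadata(oriented)$germlineIsNonTumor))
    warning("estimated fraction > 40% with the non-tumor sample as germline ",
            "reference; heterozygosity filtering may be biased")
  .MosaicEstimate(fractionPct = as.numeric(frac),
                  rawFraction = if (is.null(attr(frac, "raw")))
                    as.numeric(frac) else attr(frac, "raw"),
                  gafNT = gaf, nSnps = length(oriented), pValue = p,
                  detected = p < alpha, method = "baf", perSnp = perSnp)
}

#' Mosaic cell fraction from annotated section areas
#'
#' For stained FFPE sections the mosaic fraction is simply the annotated
#' mosaic area over the total non-tumor slide area, in percent.
#'
#' @param mosaicArea,totalArea Areas in any common unit;
#'   `0 <= mosaicArea <= totalArea`, `totalArea > 0`.
#' @return A [MosaicEstimate-class] with method `"area"`.
#' @examples
#' fractionPct(areaFraction(14, 100))  # 14
#' @export
areaFraction <- function(mosaicArea, totalArea) {
  if (totalArea <= 0) stop("totalArea must be positive")
  if (mosaicArea < 0 || mosaicArea > totalArea)
    stop("mosaicArea must lie in [0, totalArea]")
  .MosaicEstimate(fractionPct = 100 * mosaicArea / totalArea,
                  method = "area")
}
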