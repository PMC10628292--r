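#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end mcols mcols<-
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Allele copy numbers implied by each alteration class in a fully altered
## cell: cn-LOH has two copies of the gained (paternal) allele and none of the
## lost one; a paternal duplication keeps the maternal copy.
.ALTERATION_COPIES <- list(
  cn_LOH       = c(nMaj = 2L, nMin = 0L),
  paternal_dup = c(nMaj = 2L, nMin = 1L)
)

#' MosaicLocus: an altered 11p15.5-style locus
#'
#' Describes the genomic interval under test together with the alteration
#' class and the major/minor allele copy numbers carried by fully altered
#' cells. Copy numbers are fixed by the alteration class: copy-neutral LOH
#' implies (2, 0), a paternal duplication (2, 1).
#'
#' @slot region A length-1 \link[GenomicRanges]{GRanges} (1-based inclusive).
#' @slot alteration `"cn_LOH"` or `"paternal_dup"`.
#' @slot nMaj,nMin Integer copies of the major (gained) and minor allele.
#' @slot genomeBuild Free-text build label, kept as metadata only.
#'
#' @seealso [MosaicLocus()] for the user-facing constructor.
#' @exportClass MosaicLocus
setClass("MosaicLocus",
  slots = c(
    region = "GRanges",
    alteration = "character",
    nMaj = "integer",
    nMin = "integer",
    genomeBuild = "character"
  )
)

setValidity("MosaicLocus", function(object) {
  msg <- character()
  if (length(object@region) != 1L)
    msg <- c(msg, "region must contain exactly one interval")
  if (!(object@alteration %in% names(.ALTERATION_COPIES)))
    msg <- c(msg, sprintf("alteration must be one of: %s",
                          paste(names(.ALTERATION_COPIES), collapse = ", ")))
  else {
    expected <- .ALTERATION_COPIES[[object@alteration]]
    if (object@nMaj != expected[["nMaj"]] || object@nMin != expected[["nMin"]])
      msg <- c(msg, sprintf("%s requires (nMaj, nMin) = (%d, %d)",
                            object@alteration, expected[["nMaj"]],
                            expected[["nMin"]]))
  }
  if (length(object@nMaj) != 1L || object@nMaj < 1L)
    msg <- c(msg, "nMaj must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MosaicLocus
#'
#' @param chrom Chromosome label (e.g. `"chr11"`).
#' @param start,end 1-based inclusive interval bounds.
#' @param alteration `"cn_LOH"` (copy-neutral loss of heterozygosity) or
#'   `"paternal_dup"` (paternal duplication, three copies total).
#' @param genomeBuild Free-text genome build label; recorded, never
#'   interpreted.
#' @return A [MosaicLocus-class] object.
#' @examples
#' MosaicLocus("chr11", 1, 2800000, "cn_LOH")
#' @export
MosaicLocus <- function(chrom, start, end, alteration = c("cn_LOH", "paternal_dup"),
                        genomeBuild = NA_character_) {
  alteration <- match.arg(alteration)
  copies <- .ALTERATION_COPIES[[alteration]]
  new("MosaicLocus",
      region = GRanges(chrom, IRanges(start, end)),
      alteration = alteration,
      nMaj = copies[["nMaj"]],
      nMin = copies[["nMin"]],
      genomeBuild = as.character(genomeBuild))
}

#' @describeIn MosaicLocus-class The locus interval as a `GRanges`.
#' @param x,object A `MosaicLocus`.
#' @export
lociRegion <- function(x) x@region

#' @describeIn MosaicLocus-class The alteration class.
#' @export
alterationType <- function(x) x@alteration

#' @describeIn MosaicLocus-class Major/minor allele copy numbers, named.
#' @export
alleleCopies <- function(x) c(nMaj = x@nMaj, nMin = x@nMin)

setMethod("show", "MosaicLocus", function(object) {
  r <- object@region
  cat(sprintf("MosaicLocus %s:%d-%d [%s] nMaj=%d nMin=%d\n",
              as.character(seqnames(r)), start(r), end(r),
              object@alteration, object@nMaj, object@nMin))
})

#' MosaicEstimate: one mosaic-fraction measurement
#'
#' The result of quantifying the fraction of altered cells in a tissue by one
#' modality. `fractionPct` is clamped to [0, 100]; the unclamped value is kept
#' in `rawFraction` because sampling noise near a true fraction of zero
#' legitimately produces small negatives.
#'
#' @slot fractionPct Percentage of altered cells, clamped to [0, 100].
#' @slot rawFraction The unclamped estimate.
#' @slot gafNT Median non-tumor B-allele frequency of the gained alleles
#'   (NA for non-BAF modalities).
#' @slot nSnps Number of informative SNPs (0 for non-BAF modalities).
#' @slot pValue One-sided exact binomial detection p-value (NA when the
#'   modality carries no test).
#' @slot detected Logical detection flag at the alpha used.
#' @slot method One of `"baf"`, `"methylation"`, `"area"`, `"sc"`.
#' @slot perSnp A \link[S4Vectors]{DataFrame} of per-SNP diagnostics
#'   (may be empty).
#'
#' @exportClass MosaicEstimate
setClass("MosaicEstimate",
  slots = c(
    fractionPct = "numeric",
    rawFraction = "numeric",
    gafNT = "numeric",
    nSnps = "integer",
    pValue = "numeric",
    detected = "logical",
    method = "character",
    perSnp = "DataFrame"
  ),
  prototype = prototype(
    gafNT = NA_real_, nSnps = 0L, pValue = NA_real_, detected = NA,
    perSnp = S4Vectors::DataFrame()
  )
)

setValidity("MosaicEstimate", function(object) {
  msg <- character()
  if (length(object@fractionPct) != 1L ||
      object@fractionPct < 0 || object@fractionPct > 100)
    msg <- c(msg, "fractionPct must be a single value in [0, 100]")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1] or NA")
  if (object@nSnps < 0L)
    msg <- c(msg, "nSnps must be >= 0")
  if (!(object@method %in% c("baf", "methylation", "area", "sc")))
    msg <- c(msg, "method must be one of baf, methylation, area, sc")
  if (length(msg)) msg else TRUE
})

.MosaicEstimate <- function(fractionPct, rawFraction = fractionPct,
                            gafNT = NA_real_, nSnps = 0L, pValue = NA_real_,
                            detected = NA, method = "baf",
                            perSnp = S4Vectors::DataFrame()) {
  new("MosaicEstimate", fractionPct = fractionPct, rawFraction = rawFraction,
      gafNT = gafNT, nSnps = as.integer(nSnps), pValue = pValue,
      detected = detected, method = method, perSnp = perSnp)
}

#' @describeIn MosaicEstimate-class Clamped mosaic fraction (percent).
#' @param x,object A `MosaicEstimate`.
#' @export
fractionPct <- function(x) x@fractionPct

#' @describeIn MosaicEstimate-class Median non-tumor gained-allele BAF.
#' @export
gafNT <- function(x) x@gafNT

#' @describeIn MosaicEstimate-class Detection p-value.
#' @export
pValue <- function(x) x@pValue

#' @describeIn MosaicEstimate-class Number of informative SNPs used.
#' @export
nSnps <- function(x) x@nSnps

#' @describeIn MosaicEstimate-class Logical detection flag.
#' @export
isDetected <- function(x) x@detected

#' @describeIn MosaicEstimate-class Modality tag.
#' @export
estimateMethod <- function(x) x@method

setMethod("show", "MosaicEstimate", function(object) {
  cat(sprintf("MosaicEstimate [%s]: %.2f%% altered cells\n",
              object@method, object@fractionPct))
  if (!is.na(object@gafNT))
    cat(sprintf("  GAF(NT) = %.4f over %d informative SNPs\n",
                object@gafNT, object@nSnps))
  if (!is.na(object@pValue))
    cat(sprintf("  detection p = %.3g (%s)\n", object@pValue,
                if (isTRUE(object@detected)) "detected" else "not detected"))
})

#' MethylationSummary: imprinting-center methylation for one sample
#'
#' @slot sampleId Sample label.
#' @slot ic1Mean,ic2Mean Mean methylation fraction over non-excluded probes
#'   (or pooled RRBS counts) per imprinting center.
#' @slot ratio IC1/IC2 methylation ratio; 1 in balanced tissue.
#' @slot fractionPct Methylation-based mosaic fraction, clamped to [0, 100].
#' @slot rawFraction Unclamped fraction (negatives indicate IC2 > IC1).
#' @slot gomIc1,lomIc2 Epimutation calls (NA when no cohort classification
#'   was run).
#' @slot mosaicFlag Cohort-outlier flag from the IC1/IC2 ratio (NA when no
#'   normal cohort was supplied).
#' @exportClass MethylationSummary
setClass("MethylationSummary",
  slots = c(
    sampleId = "character",
    ic1Mean = "numeric",
    ic2Mean = "numeric",
    ratio = "numeric",
    fractionPct = "numeric",
    rawFraction = "numeric",
    gomIc1 = "logical",
    lomIc2 = "logical",
    mosaicFlag = "logical"
  ),
  prototype = prototype(sampleId = NA_character_, gomIc1 = NA, lomIc2 = NA,
                        mosaicFlag = NA)
)

setValidity("MethylationSummary", function(object) {
  msg <- character()
  if (object@ic1Mean < 0 || object@ic1Mean > 1 ||
      object@ic2Mean < 0 || object@ic2Mean > 1)
    msg <- c(msg, "ic1Mean and ic2Mean must be fractions in [0, 1]")
  if (object@fractionPct < 0 || object@fractionPct > 100)
    msg <- c(msg, "fractionPct must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' @describeIn MethylationSummary-class IC means, named vector.
#' @param x,object A `MethylationSummary`.
#' @export
icMeanValues <- function(x) c(ic1 = x@ic1Mean, ic2 = x@ic2Mean)

#' @describeIn MethylationSummary-class The IC1/IC2 ratio.
#' @export
icRatioValue <- function(x) x@ratio

setMethod("show", "MethylationSummary", function(object) {
  cat(sprintf("MethylationSummary%s: IC1=%.3f IC2=%.3f ratio=%.3f fraction=%.1f%%\n",
              if (is.na(object@sampleId)) "" else paste0(" [", object@sampleId, "]"),
              object@ic1Mean, object@ic2Mean, object@ratio, object@fractionPct))
  if (!is.na(object@gomIc1) || !is.na(object@lomIc2))
    cat(sprintf("  GOM-IC1: %s  LOM-IC2: %s\n", object@gomIc1, object@lomIc2))
})

#' The four IGF2 promoter categories
#'
#' `"P0-P1"` is the adult liver-specific promoter block; `"P2"`, `"P3"`,
#' `"P4"` are the fetal promoters.
#' @export
PROMOTER_CATEGORIES <- c("P0-P1", "P2", "P3", "P4")

#' PromoterUsage: adult vs fetal IGF2 promoter usage for one sample
#'
#' @slot sampleId Sample label.
#' @slot normalized Category junction depths divided by the universal-junction
#'   depth (comparable across samples).
#' @slot proportions Normalized depths rescaled to sum to 1 (NA when no
#'   category carries signal).
#' @slot fetalFraction Sum of the P2+P3+P4 proportions.
#' @exportClass PromoterUsage
setClass("PromoterUsage",
  slots = c(
    sampleId = "character",
    normalized = "numeric",
    proportions = "numeric",
    fetalFraction = "numeric"
  ),
  prototype = prototype(sampleId = NA_character_)
)

setValidity("PromoterUsage", function(object) {
  msg <- character()
  if (!identical(names(object@normalized), PROMOTER_CATEGORIES) ||
      !identical(names(object@proportions), PROMOTER_CATEGORIES))
    msg <- c(msg, "normalized and proportions must be named by the four promoter categories")
  p <- object@proportions
  if (!anyNA(p)) {
    if (abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "proportions must sum to 1")
    if (any(p < 0 | p > 1))
      msg <- c(msg, "proportions must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PromoterUsage-class Promoter-usage proportions, named vector.
#' @param x,object A `PromoterUsage`.
#' @export
usageProportions <- function(x) x@proportions

#' @describeIn PromoterUsage-class Fetal (P2+P3+P4) fraction of usage.
#' @export
fetalFraction <- function(x) x@fetalFraction

setMethod("show", "PromoterUsage", function(object) {
  cat(sprintf("PromoterUsage%s\n",
              if (is.na(object@sampleId)) "" else paste0(" [", object@sampleId, "]")))
  if (anyNA(object@proportions)) {
    cat("  no junction signal (usage absent)\n")
  } else {
    cat(sprintf("  %s\n", paste(sprintf("%s=%.3f", PROMOTER_CATEGORIES,
                                        object@proportions), collapse = " ")))
    cat(sprintf("  fetal fraction = %.3f\n", object@fetalFraction))
  }
})
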