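## MS-MLPA probe analysis, RRBS region methylation, the IC1/IC2 ratio and
## the methylation-based mosaic fraction.

#' Probe excluded from IC1 analysis by default
#'
#' One IC1-targeting probe of the BWS/RSS MS-MLPA kit whose distribution does
#' not discriminate samples with and without IC1 gain of methylation.
#' @export
DEFAULT_EXCLUDED_PROBES <- "H19.11.001.976583"

#' Assemble an MS-MLPA probe table
#'
#' @param probeId Probe identifiers.
#' @param target Per-probe target, one of `"IC1"`, `"IC2"`,
#'   `"IGF2_promoter"`.
#' @param value Methylation fractions in [0, 1].
#' @param exclude Probe identifiers to exclude from IC summaries
#'   (default [DEFAULT_EXCLUDED_PROBES]).
#' @return A `data.frame` with columns `probe_id`, `target`, `value`,
#'   `excluded`.
#' @export
mlpaProbes <- function(probeId, target, value,
                       exclude = DEFAULT_EXCLUDED_PROBES) {
  target <- as.character(target)
  if (!all(target %in% c("IC1", "IC2", "IGF2_promoter")))
    stop("target must be one of IC1, IC2, IGF2_promoter")
  if (any(is.na(value)) || any(value < 0 | value > 1))
    stop("probe values must be methylation fractions in [0, 1]")
  data.frame(probe_id = as.character(probeId), target = target,
             value = as.numeric(value),
             excluded = as.character(probeId) %in% exclude,
             stringsAsFactors = FALSE)
}

#' Mean IC1 and IC2 methylation over non-excluded probes
#'
#' @param probes A probe table from [mlpaProbes()] (one sample).
#' @return Named numeric `c(ic1 = , ic2 = )`, the arithmetic mean of
#'   non-excluded probe values per imprinting center.
#' @examples
#' p <- mlpaProbes(paste0("p", 1:7), rep(c("IC1", "IC2"), c(3, 4)),
#'                 c(0.6, 0.6, 0.6, 0.5, 0.5, 0.5, 0.5))
#' icMeans(p)
#' @export
icMeans <- function(probes) {
  stopifnot(all(c("target", "value", "excluded") %in% names(probes)))
  usable <- probes[!probes$excluded, , drop = FALSE]
  out <- vapply(c("IC1", "IC2"), function(ic) {
    v <- usable$value[usable$target == ic]
    if (length(v) == 0L)
      stop(sprintf("no non-excluded probe targets %s", ic))
    mean(v)
  }, numeric(1))
  names(out) <- c("ic1", "ic2")
  out
}

#' IC1/IC2 methylation ratio
#'
#' In balanced (non-mosaic) tissue both imprinting centers are methylated on
#' one parental allele, so the ratio is 1; paternal-allele gains raise IC1
#' and lower IC2, pushing the ratio above 1.
#'
#' @param ic1Mean,ic2Mean Mean methylation fractions; `ic2Mean > 0`.
#' @return `ic1Mean / ic2Mean`.
#' @export
icRatio <- function(ic1Mean, ic2Mean) {
  if (any(ic2Mean <= 0)) stop("ic2Mean must be positive")
  ic1Mean / ic2Mean
}

#' Methylation-based mosaic cell fraction
#'
#' Under a paternal-UPD mixture with symmetric baseline methylation b, a
#' fraction rho of altered cells (IC1 fully methylated, IC2 unmethylated)
#' yields IC1 = b(1-rho)+rho and IC2 = b(1-rho); the normalized difference
#' `100 * (IC1 - IC2)/(IC1 + IC2)` recovers 100*rho exactly when b = 0.5.
#'
#' @param ic1Mean,ic2Mean Mean methylation fractions; their sum must be
#'   positive.
#' @return Percentage of altered cells, clamped to [0, 100]; negative raw
#'   values (IC2 above IC1) are kept in the `"raw"` attribute with a
#'   warning.
#' @examples
#' mosaicFractionMethylation(0.625, 0.375)  # 25
#' @export
mosaicFractionMethylation <- function(ic1Mean, ic2Mean) {
  if (any(ic1Mean + ic2Mean <= 0))
    stop("ic1Mean + ic2Mean must be positive")
  .clampPct(100 * (ic1Mean - ic2Mean) / (ic1Mean + ic2Mean),
            context = "methylation mosaic fraction")
}

## Exact 1-D 2-means threshold. In one dimension the optimal two-cluster
## partition is a split of the sorted values, so all n-1 contiguous splits
## are scored by within-cluster sum of squares and the best taken; the
## threshold is the midpoint of the two cluster means. Exactness matters:
## iterative k-means started from fixed points can stall in a local optimum
## on probes without real structure and split the normal cluster in half.
## Returns NA for degenerate inputs (no separation).
.kmeansThreshold1d <- function(x) {
  s <- sort(as.numeric(x))
  n <- length(s)
  if (diff(range(s)) < .Machine$double.eps^0.5) return(NA_real_)
  csum <- cumsum(s); csq <- cumsum(s^2)
  i <- seq_len(n - 1)
  ssLo <- csq[i] - csum[i]^2 / i
  ssHi <- (csq[n] - csq[i]) - (csum[n] - csum[i])^2 / (n - i)
  best <- which.min(ssLo + ssHi)
  (csum[best] / best + (csum[n] - csum[best]) / (n - best)) / 2
}

#' Classify GOM-IC1 and LOM-IC2 epimutations across a cohort
#'
#' For every usable probe a two-group 1-D k-means across samples -- solved
#' exactly over all splits of the sorted values -- defines a per-probe
#' threshold (midpoint of the two cluster centers). A sample is called
#' gain-of-methylation IC1 when at least 2 of its 3 usable IC1 probes lie
#' above their thresholds, and loss-of-methylation IC2 when at least 2 of its
#' 4 IC2 probes lie below theirs ("beyond the threshold" is read in the
#' direction of the epimutation: up for an IC1 gain, down for an IC2 loss).
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param target Character vector along rows, `"IC1"` or `"IC2"` (rows with
#'   other labels are ignored).
#' @param exclude Probe ids dropped before classification
#'   (default [DEFAULT_EXCLUDED_PROBES]).
#' @param minHits Number of concordant probes required for a call
#'   (default 2, the 2/3 and 2/4 rules).
#' @return A `data.frame` with one row per sample: `sample_id`, `gom_ic1`,
#'   `lom_ic2`. Probes with no separation (all values identical) contribute
#'   no calls; if all probes of a center are degenerate the calls are all
#'   `FALSE` with a warning.
#' @export
classifyEpimutation <- function(values, target,
                                exclude = DEFAULT_EXCLUDED_PROBES,
                                minHits = 2L) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need at least 2 samples to classify")
  if (length(target) != nrow(values))
    stop("target must label every probe row")
  keep <- !(rownames(values) %in% exclude) & target %in% c("IC1", "IC2")
  values <- values[keep, , drop = FALSE]
  target <- target[keep]
  if (sum(target == "IC1") < 3L || sum(target == "IC2") < 4L)
    stop("need at least 3 usable IC1 probes and 4 IC2 probes")

  thresholds <- apply(values, 1, .kmeansThreshold1d)
  if (all(is.na(thresholds)))
    warning("degenerate cohort: no probe separates the samples")

  hits <- function(ic, loss) {
    rows <- which(target == ic & !is.na(thresholds))
    if (length(rows) == 0L) return(rep(0L, ncol(values)))
    beyond <- if (loss) values[rows, , drop = FALSE] <
      thresholds[rows] else values[rows, , drop = FALSE] > thresholds[rows]
    colSums(beyond)
  }
  data.frame(
    sample_id = colnames(values) %||% as.character(seq_len(ncol(values))),
    gom_ic1 = hits("IC1", loss = FALSE) >= minHits,
    lom_ic2 = hits("IC2", loss = TRUE) >= minHits,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a GRanges of RRBS CpG counts
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based CpG positions.
#' @param methCount,unmethCount Non-negative methylated/unmethylated
#'   cytosine counts.
#' @return A width-1 `GRanges` with `methCount` and `unmethCount` columns.
#' @export
rrbsCpgs <- function(chrom, pos, methCount, unmethCount) {
  if (any(methCount < 0) || any(unmethCount < 0))
    stop("cytosine counts must be non-negative")
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$methCount <- as.integer(methCount)
  mcols(gr)$unmethCount <- as.integer(unmethCount)
  gr
}

#' Default imprinting-center regions (hg38)
#'
#' IC1 chr11:1,998,745-2,003,509 and IC2 chr11:2,697,587-2,700,983, 1-based
#' inclusive on build hg38. Editable copies ship as a BED-like TSV in
#' `inst/extdata/ic_regions.tsv`; promoter intervals (P1-P4) are
#' study-specific and must be supplied by the user.
#'
#' @return A named `GRanges` with rows `IC1` and `IC2`.
#' @export
icRegions <- function() {
  gr <- GRanges("chr11", IRanges(c(1998745, 2697587), c(2003509, 2700983)))
  names(gr) <- c("IC1", "IC2")
  mcols(gr)$name <- names(gr)
  gr
}

#' Region methylation from pooled RRBS counts
#'
#' The region methylation level is the ratio of methylated cytosines to all
#' (methylated + unmethylated) cytosines pooled over in-region CpGs --
#' a coverage-weighted pooled ratio, not the mean of per-CpG ratios.
#'
#' @param cpgs A CpG `GRanges` from [rrbsCpgs()].
#' @param region A length-1 `GRanges` (or one row of [icRegions()]).
#' @param excludeCpgs Optional `GRanges` of CpG positions to drop before
#'   pooling (e.g. sites in protocol-biased regions).
#' @return Pooled methylation fraction, or `NA` when no covered CpG lies in
#'   the region.
#' @export
rrbsRegionMethylation <- function(cpgs, region, excludeCpgs = NULL) {
  stopifnot(all(c("methCount", "unmethCount") %in% colnames(mcols(cpgs))))
  if (!is.null(excludeCpgs))
    cpgs <- cpgs[!IRanges::overlapsAny(cpgs, excludeCpgs)]
  inRegion <- subsetByOverlaps(cpgs, region)
  meth <- sum(mcols(inRegion)$methCount)
  total <- meth + sum(mcols(inRegion)$unmethCount)
  if (total == 0) return(NA_real_)
  meth / total
}

#' Flag a sample as mosaic from its IC1/IC2 ratio against a normal cohort
#'
#' A sample is flagged when its ratio falls strictly outside
#' mean +/- `kSd` standard deviations of the presumed-normal cohort; both
#' tails are screened so that IC2-loss-driven elevation and symmetric
#' anomalies are caught.
#'
#' @param ratio The sample's IC1/IC2 ratio.
#' @param cohortRatios Ratios of presumed-normal samples.
#' @param kSd SD multiplier (default 3).
#' @return Logical flag (vectorized over `ratio`).
#' @export
classifyMosaicByRatio <- function(ratio, cohortRatios, kSd = 3) {
  m <- mean(cohortRatios)
  s <- stats::sd(cohortRatios)
  if (is.na(s) || s == 0) stop("normal cohort has zero ratio variance")
  ratio > m + kSd * s | ratio < m - kSd * s
}

#' Summarise one sample's MS-MLPA profile
#'
#' Convenience wrapper combining [icMeans()], [icRatio()] and
#' [mosaicFractionMethylation()] into a [MethylationSummary-class].
#'
#' @param probes Probe table from [mlpaProbes()].
#' @param sampleId Optional sample label.
#' @param gomIc1,lomIc2 Optional epimutation calls from
#'   [classifyEpimutation()].
#' @param cohortRatios Optional normal-cohort ratios for the outlier flag.
#' @param kSd SD multiplier for [classifyMosaicByRatio()].
#' @return A [MethylationSummary-class].
#' @export
summarizeMethylation <- function(probes, sampleId = NA_character_,
                                 gomIc1 = NA, lomIc2 = NA,
                                 cohortRatios = NULL, kSd = 3) {
  means <- icMeans(probes)
  ratio <- icRatio(means[["ic1"]], means[["ic2"]])
  frac <- suppressWarnings(
    mosaicFractionMethylation(means[["ic1"]], means[["ic2"]]))
  flag <- if (is.null(cohortRatios)) NA else
    classifyMosaicByRatio(ratio, cohortRatios, kSd)
  new("MethylationSummary", sampleId = as.character(sampleId),
      ic1Mean = means[["ic1"]], ic2Mean = means[["ic2"]], ratio = ratio,
      fractionPct = as.numeric(frac),
      rawFraction = if (is.null(attr(frac, "raw"))) as.numeric(frac)
        else attr(frac, "raw"),
      gomIc1 = gomIc1, lomIc2 = lomIc2, mosaicFlag = flag)
}
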