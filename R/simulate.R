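## Synthetic-data generators. Each generator draws from the mixture model the
## corresponding analysis stage assumes and returns the data together with a
## `truth` record, so the generators double as oracles for parameter
## recovery. Every generator takes a mandatory seed: no silent
## nondeterminism.

#' Expected gained-allele dosage under a mosaic mixture
#'
#' A fraction `rho` of cells carries `nMaj` copies of the gained allele and
#' `nMin` of the other; the remaining cells are balanced heterozygotes. The
#' expected frequency of the gained allele is then
#' `(1 + rho*(nMaj - 1)) / (2 + rho*(nMaj + nMin - 2))`:
#' `(1 + rho)/2` for cn-LOH, `(1 + rho)/(2 + rho)` for a paternal
#' duplication. This is the exact inverse of [mosaicFraction()].
#'
#' @param rho Mosaic fraction in [0, 1]; vectorized.
#' @param alteration `"cn_LOH"` or `"paternal_dup"`.
#' @return Expected gained-allele frequency.
#' @export
gainedDosage <- function(rho, alteration = c("cn_LOH", "paternal_dup")) {
  alteration <- match.arg(alteration)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  copies <- .ALTERATION_COPIES[[alteration]]
  nMaj <- copies[["nMaj"]]; nMin <- copies[["nMin"]]
  (1 + rho * (nMaj - 1)) / (2 + rho * (nMaj + nMin - 2))
}

## Beta-binomial sampler (overdispersion rho_bb in (0,1)); falls back to
## binomial at rho_bb = 0. Real capture data are overdispersed relative to
## binomial, so the option is provided even though the default model is
## binomial.
.rcounts <- function(n, size, prob, overdispersion = 0) {
  if (overdispersion <= 0) return(stats::rbinom(n, size, prob))
  conc <- (1 - overdispersion) / overdispersion
  p <- stats::rbeta(n, prob * conc, (1 - prob) * conc)
  stats::rbinom(n, size, p)
}

#' Simulate matched non-tumor/tumor SNP allele depths under mosaicism
#'
#' Germline-heterozygous SNPs are placed uniformly in the locus; per SNP the
#' sequencing depth is Poisson around the target mean and the gained-allele
#' read count is binomial at the mixture dosage ([gainedDosage()]). The
#' gained allele is the alternate or reference allele with equal probability
#' per SNP (recorded in the truth record). The tumor is simulated as fully
#' altered at purity `tumorPurity`, i.e. at dosage
#' `gainedDosage(tumorPurity, alteration)`.
#'
#' @param rho True mosaic fraction in the non-tumor tissue.
#' @param alteration `"cn_LOH"` or `"paternal_dup"`.
#' @param nSnps Number of heterozygous SNPs (default 5000).
#' @param depthNt,depthT Mean sequencing depths (defaults 30 and 90).
#' @param tumorPurity Tumor purity (default 1).
#' @param depthGermline Mean depth of an additional unaltered germline
#'   (blood-like) sample emitted for heterozygosity filtering
#'   (default `depthNt`). Its BAF is balanced (dosage 0.5) at every SNP.
#' @param overdispersion Optional beta-binomial overdispersion in [0, 1);
#'   0 (default) gives pure binomial sampling.
#' @param locus The [MosaicLocus-class] to simulate within (default: a
#'   cn-LOH/paternal-dup locus on chr11:1-2,800,000 matching `alteration`).
#' @param seed Mandatory integer seed.
#' @return A list with `sites` (SNP-site `GRanges`, see [snpSites()]),
#'   `locus`, `germline` (list with per-SNP `baf` and `depth` of the
#'   blood-like sample) and `truth` (list with `rho`, `alteration`,
#'   `gainedIsAlt`).
#' @export
simulateBulkSnps <- function(rho, alteration = c("cn_LOH", "paternal_dup"),
                             nSnps = 5000, depthNt = 30, depthT = 90,
                             tumorPurity = 1, depthGermline = depthNt,
                             overdispersion = 0, locus = NULL, seed) {
  alteration <- match.arg(alteration)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (is.null(locus))
    locus <- MosaicLocus("chr11", 1, 2800000, alteration)
  region <- lociRegion(locus)
  pos <- sort(sample(seq(start(region), end(region)), nSnps))

  gainedIsAlt <- stats::runif(nSnps) < 0.5
  dNT <- stats::rpois(nSnps, depthNt)
  dT <- stats::rpois(nSnps, depthT)
  doseNT <- gainedDosage(rho, alteration)
  doseT <- gainedDosage(tumorPurity, alteration)
  gainedNT <- .rcounts(nSnps, dNT, doseNT, overdispersion)
  gainedT <- .rcounts(nSnps, dT, doseT, overdispersion)

  altNT <- ifelse(gainedIsAlt, gainedNT, dNT - gainedNT)
  altT <- ifelse(gainedIsAlt, gainedT, dT - gainedT)
  sites <- snpSites(as.character(seqnames(region)), pos,
                    refNT = dNT - altNT, altNT = altNT,
                    refT = dT - altT, altT = altT)
  dG <- stats::rpois(nSnps, depthGermline)
  altG <- .rcounts(nSnps, dG, 0.5, overdispersion)
  list(sites = sites, locus = locus,
       germline = list(baf = computeBaf(dG - altG, altG), depth = dG),
       truth = list(rho = rho, alteration = alteration,
                    gainedIsAlt = gainedIsAlt))
}

## Mixture IC means: fully altered cells have IC1 = 1, IC2 = 0 (cn-LOH or
## paternal UPD), an IC2 epimutation only erases IC2, an IC1 epimutation
## only saturates IC1.
.icMixtureMeans <- function(rho, alteration, baseline) {
  ic1 <- switch(alteration,
    cn_LOH = , paternal_dup = , epi_IC1 = baseline * (1 - rho) + rho,
    epi_IC2 = baseline)
  ic2 <- switch(alteration,
    cn_LOH = , paternal_dup = , epi_IC2 = baseline * (1 - rho),
    epi_IC1 = baseline)
  c(ic1 = ic1, ic2 = ic2)
}

#' Simulate an MS-MLPA probe cohort
#'
#' Per sample, probe values are the mixture means implied by that sample's
#' mosaic fraction and alteration class plus truncated Gaussian probe noise.
#' The probe panel mirrors the BWS/RSS kit: 4 IC1 probes (one excluded by
#' default, see [DEFAULT_EXCLUDED_PROBES]), 4 IC2 probes and 2 IGF2-promoter
#' probes.
#'
#' @param rho Per-sample mosaic fractions (length = number of samples).
#' @param alteration Per-sample alteration class, one of `"cn_LOH"`,
#'   `"paternal_dup"`, `"epi_IC1"`, `"epi_IC2"` (recycled).
#' @param baseline Baseline methylation of both ICs in unaltered cells
#'   (default 0.5, the symmetric imprinting baseline; ~0.6 is observed in
#'   fetal liver and can be simulated instead).
#' @param probeNoiseSd Gaussian probe noise SD (default 0.05).
#' @param seed Mandatory integer seed.
#' @return A list with `probes` (long `data.frame`: `sample_id`, `probe_id`,
#'   `target`, `value`), `values` (probe-by-sample matrix),
#'   `target` (per-row targets of `values`) and `truth`
#'   (`data.frame` with per-sample `rho` and `alteration`).
#' @export
simulateMethylationCohort <- function(rho, alteration = "cn_LOH",
                                      baseline = 0.5, probeNoiseSd = 0.05,
                                      seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  nSamples <- length(rho)
  alteration <- rep_len(alteration, nSamples)
  stopifnot(all(alteration %in% c("cn_LOH", "paternal_dup", "epi_IC1",
                                  "epi_IC2")))
  probeIds <- c(DEFAULT_EXCLUDED_PROBES, paste0("IC1_p", 2:4),
                paste0("IC2_p", 1:4), paste0("IGF2prom_p", 1:2))
  target <- rep(c("IC1", "IC2", "IGF2_promoter"), c(4, 4, 2))

  values <- matrix(NA_real_, nrow = length(probeIds), ncol = nSamples,
                   dimnames = list(probeIds,
                                   sprintf("S%03d", seq_len(nSamples))))
  for (j in seq_len(nSamples)) {
    mix <- .icMixtureMeans(rho[j], alteration[j], baseline)
    mu <- c(rep(mix[["ic1"]], 4), rep(mix[["ic2"]], 4), rep(baseline, 2))
    values[, j] <- pmin(pmax(mu + stats::rnorm(length(mu), 0, probeNoiseSd),
                             0), 1)
  }
  probes <- data.frame(
    sample_id = rep(colnames(values), each = length(probeIds)),
    probe_id = rep(probeIds, nSamples),
    target = rep(target, nSamples),
    value = as.vector(values),
    stringsAsFactors = FALSE)
  list(probes = probes, values = values, target = target,
       truth = data.frame(sample_id = colnames(values), rho = rho,
                          alteration = alteration,
                          stringsAsFactors = FALSE))
}

#' Simulate per-cell per-SNP allele counts under mosaic cn-LOH
#'
#' Each cell carries the cn-LOH with probability `rho`; its informative read
#' count is Poisson, reads are spread uniformly over a panel of phased SNPs,
#' and each read reports the paternal allele with probability
#' `1 - errorRate` in LOH cells and 0.5 in balanced cells.
#'
#' @param rho Fraction of LOH cells.
#' @param nCells Number of cells (default 500).
#' @param readsPerCellMean Mean informative reads per cell (default 20).
#' @param errorRate Probability that a read from an LOH cell reports the
#'   maternal allele (sequencing error / ambient contamination; default
#'   0.02, must be < 0.5).
#' @param nSnps Size of the phased SNP panel (default 20).
#' @param seed Mandatory integer seed.
#' @return A list with `counts` (`data.frame`: `cell_id`, `chrom`, `pos`,
#'   `allele`, `count`), `phased` (phasing `data.frame`), and `truth`
#'   (`data.frame`: `cell_id`, `is_loh`).
#' @export
simulateCells <- function(rho, nCells = 500, readsPerCellMean = 20,
                          errorRate = 0.02, nSnps = 20, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (errorRate >= 0.5) stop("errorRate must be below 0.5")
  set.seed(seed)
  pos <- sort(sample(1998745:2800000, nSnps))
  ## alternate which base is paternal so phasing, not allele identity,
  ## drives the counts
  patIsAlt <- rep_len(c(TRUE, FALSE), nSnps)
  phased <- data.frame(chrom = "chr11", pos = pos,
                       pat_allele = ifelse(patIsAlt, "alt", "ref"),
                       mat_allele = ifelse(patIsAlt, "ref", "alt"),
                       stringsAsFactors = FALSE)

  isLoh <- stats::runif(nCells) < rho
  totalReads <- stats::rpois(nCells, readsPerCellMean)
  cellIds <- sprintf("cell%05d", seq_len(nCells))

  rows <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    if (totalReads[i] == 0L) next
    snpIdx <- sample.int(nSnps, totalReads[i], replace = TRUE)
    isPat <- stats::runif(totalReads[i]) <
      (if (isLoh[i]) 1 - errorRate else 0.5)
    allele <- ifelse(isPat, phased$pat_allele[snpIdx],
                     phased$mat_allele[snpIdx])
    tab <- table(snpIdx, allele)
    idx <- as.integer(rownames(tab))
    rows[[i]] <- data.frame(
      cell_id = cellIds[i],
      chrom = "chr11",
      pos = rep(phased$pos[idx], ncol(tab)),
      allele = rep(colnames(tab), each = length(idx)),
      count = as.vector(tab),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  counts <- counts[counts$count > 0, , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, phased = phased,
       truth = data.frame(cell_id = cellIds, is_loh = isLoh,
                          total_reads = totalReads,
                          stringsAsFactors = FALSE))
}

#' Simulate splice-junction depths under a fixed promoter-usage vector
#'
#' Category read counts are multinomial over the four promoter categories at
#' the given total depth; the universal-junction depth is fixed at
#' `universalDepth`.
#'
#' @param usage Usage vector over [PROMOTER_CATEGORIES] summing to 1.
#' @param totalDepth Total category reads (default 10000).
#' @param universalDepth Universal junction depth (default `totalDepth`).
#' @param seed Mandatory integer seed.
#' @return A list with `junctions` (a [junctionCounts()] object) and
#'   `truth` (the usage vector).
#' @export
simulateJunctions <- function(usage, totalDepth = 10000,
                              universalDepth = totalDepth, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(usage) != 4L || abs(sum(usage) - 1) > 1e-9)
    stop("usage must be 4 proportions summing to 1")
  set.seed(seed)
  depths <- if (totalDepth > 0)
    as.numeric(stats::rmultinom(1, totalDepth, usage)) else rep(0, 4)
  names(depths) <- PROMOTER_CATEGORIES
  list(junctions = junctionCounts(depths, universalDepth),
       truth = stats::setNames(as.numeric(usage), PROMOTER_CATEGORIES))
}
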