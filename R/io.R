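## File formats: TSV dialects (UTF-8, tab-delimited, mandatory header,
## missing values as empty strings), VCF ingestion via VariantAnnotation,
## BED locus definitions via rtracklayer (0-based half-open converted to
## 1-based inclusive on read).

#' @importFrom utils read.delim write.table packageVersion
NULL

#' Read a tab-delimited table
#'
#' @param path File path.
#' @param requiredCols Column names that must be present.
#' @return A `data.frame`; empty files yield an empty frame with a warning.
#' @export
readTsv <- function(path, requiredCols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                  check.names = FALSE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
  if (nrow(d) == 0L) warning("empty table: ", path)
  if (!is.null(requiredCols)) {
    missing <- setdiff(requiredCols, names(d))
    if (length(missing))
      stop(path, " lacks required columns: ", paste(missing, collapse = ", "))
  }
  d
}

#' Write a tab-delimited table
#'
#' @param d A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

## Reject malformed rows with their (1-based, header-inclusive) line
## numbers.
.rejectRows <- function(bad, path, why) {
  if (any(bad))
    stop(sprintf("%s: %s at line(s) %s", path, why,
                 paste(which(bad) + 1L, collapse = ", ")))
}

#' Read SNP allele depths from a TSV or VCF
#'
#' The TSV dialect has columns `chrom`, `pos`, `ref_nt`, `alt_nt`, `ref_t`,
#' `alt_t`. VCF input must carry a per-sample allele-depth (`AD`) FORMAT
#' field in ref,alt order; the non-tumor and tumor samples are selected by
#' name or index.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param ntSample,tumorSample Sample names or indices in the VCF (defaults:
#'   first and second sample).
#' @return A SNP-site `GRanges` (see [snpSites()]).
#' @export
readVariantTable <- function(path, format = c("auto", "tsv", "vcf"),
                             ntSample = 1, tumorSample = 2) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "tsv") {
    d <- readTsv(path, c("chrom", "pos", "ref_nt", "alt_nt", "ref_t",
                         "alt_t"))
    if (nrow(d) == 0L)
      return(snpSites(character(), integer(), integer(), integer(),
                      integer(), integer()))
    countCols <- c("ref_nt", "alt_nt", "ref_t", "alt_t")
    for (cc in c("pos", countCols))
      suppressWarnings(d[[cc]] <- as.numeric(d[[cc]]))
    bad <- Reduce(`|`, lapply(d[countCols], function(v) is.na(v) | v < 0)) |
      is.na(d$pos) | d$pos < 1
    .rejectRows(bad, path, "negative or non-numeric counts/positions")
    return(snpSites(d$chrom, d$pos, d$ref_nt, d$alt_nt, d$ref_t, d$alt_t,
                    ref = d[["ref"]], alt = d[["alt"]]))
  }
  .readVariantVcf(path, ntSample, tumorSample)
}

.readVariantVcf <- function(path, ntSample, tumorSample) {
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad))
    stop(path, ": VCF lacks the AD (allele depth) FORMAT field")
  smp <- colnames(ad)
  pick <- function(s) {
    if (is.character(s)) {
      if (!(s %in% smp)) stop("sample not in VCF: ", s)
      return(match(s, smp))
    }
    if (s > length(smp)) stop("VCF has only ", length(smp), " sample(s)")
    s
  }
  iNT <- pick(ntSample); iT <- pick(tumorSample)
  getAd <- function(i, allele) {
    col <- ad[, i]
    unname(vapply(col, function(v) {
      if (length(v) < 2L || anyNA(v[seq_len(2)])) NA_integer_
      else as.integer(v[allele])
    }, integer(1)))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  refNT <- getAd(iNT, 1L); altNT <- getAd(iNT, 2L)
  refT <- getAd(iT, 1L); altT <- getAd(iT, 2L)
  ok <- !(is.na(refNT) | is.na(altNT) | is.na(refT) | is.na(altT))
  snpSites(as.character(seqnames(rr))[ok], start(rr)[ok],
           refNT[ok], altNT[ok], refT[ok], altT[ok],
           ref = as.character(rr$REF)[ok],
           alt = vapply(rr$ALT[ok], function(a) as.character(a)[1],
                        character(1)))
}

#' Read a locus definition from a BED or TSV file
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates on read; the TSV dialect (`name`, `chrom`, `start`, `end`)
#' is already 1-based inclusive.
#'
#' @param path BED or TSV file; the first record is used.
#' @param alteration Alteration tag for the locus.
#' @param genomeBuild Free-text build label.
#' @return A [MosaicLocus-class].
#' @export
readLocusBed <- function(path, alteration = c("cn_LOH", "paternal_dup"),
                         genomeBuild = NA_character_) {
  alteration <- match.arg(alteration)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
  } else {
    d <- readTsv(path, c("chrom", "start", "end"))
    gr <- GRanges(d$chrom, IRanges(as.numeric(d$start), as.numeric(d$end)))
  }
  if (length(gr) == 0L) stop("no locus records in ", path)
  MosaicLocus(as.character(seqnames(gr))[1], start(gr)[1], end(gr)[1],
              alteration, genomeBuild = genomeBuild)
}

#' Read imprinting-center / promoter regions from a BED-like TSV
#'
#' @param path TSV with columns `name`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return A named `GRanges`.
#' @export
readRegionsTsv <- function(path) {
  d <- readTsv(path, c("name", "chrom", "start", "end"))
  gr <- GRanges(d$chrom, IRanges(as.numeric(d$start), as.numeric(d$end)))
  names(gr) <- d$name
  mcols(gr)$name <- d$name
  gr
}

#' Write the SNP-site TSV dialect
#'
#' @param sites SNP-site `GRanges`.
#' @param path Output path.
#' @export
writeSnpTsv <- function(sites, path) {
  .assertSnpSites(sites)
  writeTsv(data.frame(chrom = as.character(seqnames(sites)),
                      pos = start(sites),
                      ref_nt = mcols(sites)$refNT,
                      alt_nt = mcols(sites)$altNT,
                      ref_t = mcols(sites)$refT,
                      alt_t = mcols(sites)$altT,
                      stringsAsFactors = FALSE), path)
}

#' Cross-modality concordance of mosaic-fraction estimates
#'
#' @param estimates A `data.frame` with columns `sample_id`, `method`,
#'   `fraction_pct` (optionally `p_value`).
#' @return A list with `estimates` (the per-(sample, method) rows) and
#'   `spread` (per sample: number of modalities, min, max and min-max
#'   spread of the fraction).
#' @export
buildConcordance <- function(estimates) {
  stopifnot(all(c("sample_id", "method", "fraction_pct") %in%
                  names(estimates)), nrow(estimates) >= 1L)
  spread <- do.call(rbind, lapply(split(estimates, estimates$sample_id),
                                  function(d) {
    data.frame(sample_id = d$sample_id[1], n_methods = nrow(d),
               min_fraction = min(d$fraction_pct),
               max_fraction = max(d$fraction_pct),
               spread = max(d$fraction_pct) - min(d$fraction_pct),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(estimates = estimates, spread = spread)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are kept as
#' strings (numeric coercion happens at use).
#'
#' @param path Config file path.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) trimws(m[2]), character(1)))
}

.cfgNum <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

#' Run the detection/quantification pipeline from a configuration
#'
#' Executes every stage whose inputs are configured, writes one TSV per
#' stage plus a cross-modality concordance report and a structured
#' `key=value` log, and is byte-deterministic under a fixed seed.
#'
#' Recognized keys (all optional unless a stage needs them): `seed`;
#' `simulate_rho`, `simulate_alteration`, `simulate_n_snps` (simulate a bulk
#' SNP table first); `variants` (+ `variants_format`), `locus_chrom`,
#' `locus_start`, `locus_end`, `alteration`, `alpha`, `het_low`, `het_high`,
#' `min_depth` (bulk detection); `mlpa`, `k_sd` (methylation); `phased`,
#' `cell_counts`, `cell_types`, `sample_is_altered`, `min_reads`,
#' `loh_baf`, `ref_baf` (single-nucleus calling); `junctions`,
#' `category_map` (promoter usage); `sample_id` (report label).
#'
#' @param config A named list or path to a flat key=value file
#'   ([readRunConfig()]).
#' @param outDir Output directory (created if absent).
#' @return Named character vector of written file paths, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  stopifnot(is.list(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## fail on missing inputs before any stage runs
  pathKeys <- c("variants", "mlpa", "phased", "cell_counts", "cell_types",
                "junctions", "category_map")
  for (k in pathKeys)
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("configured input does not exist: ", k, " = ", config[[k]])

  seed <- as.integer(.cfgNum(config, "seed", 1))
  sampleId <- config[["sample_id"]] %||% "sample"
  out <- character()
  logLines <- c(sprintf("package=mosaic11p version=%s",
                        as.character(packageVersion("mosaic11p"))),
                sprintf("seed=%d", seed))
  estimates <- data.frame(sample_id = character(), method = character(),
                          fraction_pct = numeric(),
                          stringsAsFactors = FALSE)

  if (!is.null(config[["simulate_rho"]])) {
    alt <- config[["simulate_alteration"]] %||% "cn_LOH"
    sim <- simulateBulkSnps(as.numeric(config[["simulate_rho"]]),
                            alteration = alt,
                            nSnps = .cfgNum(config, "simulate_n_snps", 5000),
                            seed = seed)
    p <- file.path(outDir, "simulated_snps.tsv")
    writeSnpTsv(sim$sites, p)
    out["simulate"] <- p
    config$variants <- p
    config$alteration <- alt
    config$locus_chrom <- as.character(seqnames(lociRegion(sim$locus)))
    config$locus_start <- start(lociRegion(sim$locus))
    config$locus_end <- end(lociRegion(sim$locus))
    logLines <- c(logLines, sprintf("stage=simulate rho=%s n_snps=%d",
                                    config[["simulate_rho"]],
                                    length(sim$sites)))
  }

  if (!is.null(config[["variants"]])) {
    locus <- MosaicLocus(config[["locus_chrom"]] %||% "chr11",
                         .cfgNum(config, "locus_start", 1),
                         .cfgNum(config, "locus_end", 2800000),
                         config[["alteration"]] %||% "cn_LOH")
    sites <- readVariantTable(config[["variants"]])
    oriented <- orientGainedAlleles(
      sites, locus,
      hetLow = .cfgNum(config, "het_low", 0.2),
      hetHigh = .cfgNum(config, "het_high", 0.8),
      minDepth = .cfgNum(config, "min_depth", 8))
    est <- suppressWarnings(
      detectMosaicism(oriented, locus, alpha = .cfgNum(config, "alpha", 0.05)))
    p <- file.path(outDir, "bulk_detect.tsv")
    writeTsv(data.frame(sample_id = sampleId,
                        gaf_nt = gafNT(est), fraction_pct = fractionPct(est),
                        n_snps = nSnps(est), p_value = pValue(est),
                        detected = isDetected(est),
                        stringsAsFactors = FALSE), p)
    out["bulk_detect"] <- p
    estimates <- rbind(estimates,
                       data.frame(sample_id = sampleId, method = "baf",
                                  fraction_pct = fractionPct(est),
                                  stringsAsFactors = FALSE))
    logLines <- c(logLines, sprintf("stage=bulk_detect n_snps=%d p=%g",
                                    nSnps(est), pValue(est)))
  }

  if (!is.null(config[["mlpa"]])) {
    long <- readTsv(config[["mlpa"]],
                    c("sample_id", "probe_id", "target", "value"))
    bySample <- split(long, long$sample_id)
    calls <- NULL
    if (length(bySample) >= 2L) {
      values <- do.call(cbind, lapply(bySample, function(d)
        d$value[match(unique(long$probe_id), d$probe_id)]))
      rownames(values) <- unique(long$probe_id)
      target <- long$target[match(rownames(values), long$probe_id)]
      calls <- classifyEpimutation(values, target)
    }
    rows <- do.call(rbind, lapply(names(bySample), function(sid) {
      d <- bySample[[sid]]
      s <- summarizeMethylation(
        mlpaProbes(d$probe_id, d$target, d$value), sampleId = sid,
        gomIc1 = if (is.null(calls)) NA else
          calls$gom_ic1[match(sid, calls$sample_id)],
        lomIc2 = if (is.null(calls)) NA else
          calls$lom_ic2[match(sid, calls$sample_id)])
      data.frame(sample_id = sid, ic1_mean = s@ic1Mean, ic2_mean = s@ic2Mean,
                 ratio = s@ratio, fraction_pct = s@fractionPct,
                 gom_ic1 = s@gomIc1, lom_ic2 = s@lomIc2,
                 stringsAsFactors = FALSE)
    }))
    p <- file.path(outDir, "methylation.tsv")
    writeTsv(rows, p)
    out["methylation"] <- p
    estimates <- rbind(estimates,
                       data.frame(sample_id = rows$sample_id,
                                  method = "methylation",
                                  fraction_pct = rows$fraction_pct,
                                  stringsAsFactors = FALSE))
    logLines <- c(logLines, sprintf("stage=methylation n_samples=%d",
                                    nrow(rows)))
  }

  if (!is.null(config[["phased"]]) && !is.null(config[["cell_counts"]])) {
    phased <- readTsv(config[["phased"]],
                      c("chrom", "pos", "pat_allele", "mat_allele"))
    counts <- readTsv(config[["cell_counts"]],
                      c("cell_id", "chrom", "pos", "allele", "count"))
    cellTypes <- if (!is.null(config[["cell_types"]]))
      readTsv(config[["cell_types"]], c("cell_id", "cell_type")) else NULL
    cells <- aggregateCellCounts(counts, phased, cellTypes)
    cells <- annotateReferenceSample(
      cells,
      sampleIsAltered = !identical(config[["sample_is_altered"]], "false"),
      minReads = .cfgNum(config, "min_reads", 8),
      lohBaf = .cfgNum(config, "loh_baf", 0.85),
      refBaf = .cfgNum(config, "ref_baf", 0.60))
    p <- file.path(outDir, "cells.tsv")
    writeTsv(cells, p)
    out["cells"] <- p
    if (!is.null(cells$cell_type)) {
      p2 <- file.path(outDir, "celltype_summary.tsv")
      writeTsv(summarizeByCellType(cells), p2)
      out["celltype_summary"] <- p2
    }
    det <- cells$call != "unknown"
    frac <- if (any(det)) 100 * mean(cells$call[det] == "cn_LOH") else 0
    estimates <- rbind(estimates,
                       data.frame(sample_id = sampleId, method = "sc",
                                  fraction_pct = frac,
                                  stringsAsFactors = FALSE))
    logLines <- c(logLines, sprintf("stage=sc n_cells=%d n_unknown=%d",
                                    nrow(cells), sum(!det)))
  }

  if (!is.null(config[["junctions"]]) && !is.null(config[["category_map"]])) {
    jt <- readTsv(config[["junctions"]],
                  c("sample_id", "junction_id", "depth"))
    cmap <- readTsv(config[["category_map"]], c("junction_id", "category"))
    jcs <- summarizeJunctionTable(jt, cmap)
    rows <- do.call(rbind, lapply(names(jcs), function(sid) {
      u <- promoterUsage(jcs[[sid]], sampleId = sid)
      pr <- usageProportions(u)
      data.frame(sample_id = sid, p0_p1 = pr[["P0-P1"]], p2 = pr[["P2"]],
                 p3 = pr[["P3"]], p4 = pr[["P4"]],
                 fetal_fraction = fetalFraction(u),
                 stringsAsFactors = FALSE)
    }))
    p <- file.path(outDir, "promoter_usage.tsv")
    writeTsv(rows, p)
    out["promoter_usage"] <- p
    logLines <- c(logLines, sprintf("stage=promoters n_samples=%d",
                                    nrow(rows)))
  }

  if (nrow(estimates) >= 1L) {
    conc <- buildConcordance(estimates)
    p <- file.path(outDir, "concordance.tsv")
    writeTsv(merge(conc$estimates, conc$spread, by = "sample_id"), p)
    out["concordance"] <- p
  }

  logPath <- file.path(outDir, "run_log.txt")
  writeLines(logLines, logPath, useBytes = TRUE)
  out["log"] <- logPath
  invisible(out)
}
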