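## Per-nucleus copy-neutral LOH genotyping from tumor-phased SNP allele
## counts.

#' Phase SNPs into paternal (duplicated) and maternal (lost) alleles
#'
#' Germline-heterozygous SNPs (non-tumor filter as in
#' [orientGainedAlleles()]) whose tumor BAF is strictly off 0.5 are phased
#' against the tumor disequilibrium: the majority tumor allele is paternal
#' (duplicated), the minority allele maternal (lost).
#'
#' @inheritParams orientGainedAlleles
#' @return A `GRanges` with character columns `patAllele` and `matAllele`.
#'   These are allele labels: the `ref`/`alt` bases when the sites carry
#'   them, otherwise the literal labels `"ref"`/`"alt"`.
#' @export
assignParentalAlleles <- function(sites, locus, hetLow = 0.2, hetHigh = 0.8,
                                  minDepth = 8) {
  oriented <- suppressWarnings(
    orientGainedAlleles(sites, locus, hetLow, hetHigh, minDepth))
  if (length(oriented) == 0L)
    stop("no phasable SNPs after heterozygosity and orientation filters")
  hasBases <- all(c("ref", "alt") %in% colnames(mcols(oriented)))
  refLab <- if (hasBases) mcols(oriented)$ref else rep("ref", length(oriented))
  altLab <- if (hasBases) mcols(oriented)$alt else rep("alt", length(oriented))
  gainedIsAlt <- mcols(oriented)$gainedIsAlt
  phased <- oriented
  mcols(phased) <- NULL
  mcols(phased)$patAllele <- ifelse(gainedIsAlt, altLab, refLab)
  mcols(phased)$matAllele <- ifelse(gainedIsAlt, refLab, altLab)
  phased
}

#' Sum paternal and maternal reads per cell
#'
#' Joins a per-cell per-SNP allele count table onto the phased SNPs and sums
#' paternal and maternal reads per cell; the per-cell BAF is
#' PAT/(PAT + MAT), undefined (NA) for cells without informative reads.
#' Counts at alleles matching neither the paternal nor the maternal label of
#' their SNP (e.g. sequencing errors) are dropped, as are counts at
#' positions absent from the phased set.
#'
#' @param counts A `data.frame` with columns `cell_id`, `chrom`, `pos`,
#'   `allele`, `count`.
#' @param phased Phased SNPs from [assignParentalAlleles()] or a
#'   `data.frame` with columns `chrom`, `pos`, `pat_allele`, `mat_allele`.
#' @param cellTypes Optional `data.frame` with columns `cell_id`,
#'   `cell_type`.
#' @return A `data.frame` with one row per cell: `cell_id`, `pat_reads`,
#'   `mat_reads`, `baf_cell` (and `cell_type` when supplied).
#' @export
aggregateCellCounts <- function(counts, phased, cellTypes = NULL) {
  stopifnot(all(c("cell_id", "chrom", "pos", "allele", "count") %in%
                  names(counts)))
  if (is(phased, "GRanges")) {
    phased <- data.frame(chrom = as.character(seqnames(phased)),
                         pos = start(phased),
                         pat_allele = mcols(phased)$patAllele,
                         mat_allele = mcols(phased)$matAllele,
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "pos", "pat_allele", "mat_allele") %in%
                  names(phased)))
  if (any(counts$count < 0)) stop("allele counts must be non-negative")

  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  idx <- match(key(counts$chrom, counts$pos), key(phased$chrom, phased$pos))
  matched <- !is.na(idx)
  allele <- as.character(counts$allele)
  parent <- rep(NA_character_, nrow(counts))
  parent[matched][allele[matched] == phased$pat_allele[idx[matched]]] <- "PAT"
  parent[matched][allele[matched] == phased$mat_allele[idx[matched]]] <- "MAT"
  dropped <- sum(counts$count[is.na(parent)])
  if (dropped > 0)
    message(sprintf("dropped %d reads at unphased positions or unmatched alleles",
                    dropped))

  cells <- unique(as.character(counts$cell_id))
  pat <- vapply(split(counts$count[which(parent == "PAT")],
                      factor(counts$cell_id[which(parent == "PAT")],
                             levels = cells)), sum, numeric(1))
  mat <- vapply(split(counts$count[which(parent == "MAT")],
                      factor(counts$cell_id[which(parent == "MAT")],
                             levels = cells)), sum, numeric(1))
  out <- data.frame(cell_id = cells, pat_reads = as.integer(pat),
                    mat_reads = as.integer(mat), stringsAsFactors = FALSE)
  total <- out$pat_reads + out$mat_reads
  out$baf_cell <- ifelse(total > 0, out$pat_reads / total, NA_real_)
  if (!is.null(cellTypes)) {
    stopifnot(all(c("cell_id", "cell_type") %in% names(cellTypes)))
    out$cell_type <- cellTypes$cell_type[match(out$cell_id,
                                               cellTypes$cell_id)]
  }
  out
}

#' Call copy-neutral LOH in single nuclei
#'
#' A cell with fewer than `minReads` informative reads is `"unknown"`; with
#' enough reads it is called `"cn_LOH"` when its BAF (PAT/(PAT+MAT)) is at
#' least `lohBaf`, `"no_cnLOH"` when at most `refBaf`, and `"unknown"` in
#' between. Both boundaries are inclusive.
#'
#' @param patReads,matReads Summed paternal/maternal read counts
#'   (vectorized).
#' @param minReads Minimum informative reads (default 8).
#' @param lohBaf Lower BAF bound for a cn-LOH call (default 0.85).
#' @param refBaf Upper BAF bound for a no-cn-LOH call (default 0.60).
#' @return Character vector of calls in
#'   `{"cn_LOH", "no_cnLOH", "unknown"}`.
#' @examples
#' callCell(c(10, 4, 7, 5), c(0, 4, 2, 2))
#' @export
callCell <- function(patReads, matReads, minReads = 8, lohBaf = 0.85,
                     refBaf = 0.60) {
  if (refBaf >= lohBaf) stop("refBaf must be below lohBaf")
  total <- patReads + matReads
  baf <- ifelse(total > 0, patReads / total, NA_real_)
  out <- rep("unknown", length(total))
  enough <- total >= minReads
  out[enough & baf >= lohBaf] <- "cn_LOH"
  out[enough & baf <= refBaf] <- "no_cnLOH"
  out
}

#' Call every cell of a sample, honoring an unaltered reference sample
#'
#' Cells from a sample whose tumor carries no 11p15.5 alteration are all
#' labeled `"no_cnLOH"` regardless of their counts; cells from altered
#' samples fall through to [callCell()].
#'
#' @param cells Per-cell table from [aggregateCellCounts()].
#' @param sampleIsAltered Logical: does this sample's tumor carry the
#'   alteration?
#' @inheritParams callCell
#' @return `cells` with an appended `call` column.
#' @export
annotateReferenceSample <- function(cells, sampleIsAltered, minReads = 8,
                                    lohBaf = 0.85, refBaf = 0.60) {
  cells$call <- if (isTRUE(sampleIsAltered)) {
    callCell(cells$pat_reads, cells$mat_reads, minReads, lohBaf, refBaf)
  } else {
    rep("no_cnLOH", nrow(cells))
  }
  cells
}

#' Summarise calls and per-cell BAF by cell type
#'
#' @param cells Per-cell table with `call` and `cell_type` columns (see
#'   [annotateReferenceSample()] and [aggregateCellCounts()]).
#' @return A `data.frame` with one row per cell type: `cell_type`,
#'   `n_cells`, `mean_baf` (over cells with a defined BAF), `n_cnloh`,
#'   `n_no_cnloh`, `n_unknown`, and `frac_cnloh` -- the cn-LOH fraction over
#'   determinate (non-unknown) calls, 0 when every call is unknown.
#' @export
summarizeByCellType <- function(cells) {
  stopifnot(all(c("cell_type", "call", "baf_cell") %in% names(cells)))
  do.call(rbind, lapply(split(cells, cells$cell_type), function(d) {
    nL <- sum(d$call == "cn_LOH")
    nN <- sum(d$call == "no_cnLOH")
    nU <- sum(d$call == "unknown")
    data.frame(
      cell_type = d$cell_type[1], n_cells = nrow(d),
      mean_baf = if (all(is.na(d$baf_cell))) NA_real_ else
        mean(d$baf_cell, na.rm = TRUE),
      n_cnloh = nL, n_no_cnloh = nN, n_unknown = nU,
      frac_cnloh = if (nL + nN > 0) nL / (nL + nN) else 0,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
}
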