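#' Build a GRanges of SNP sites with matched non-tumor/tumor allele depths
#'
#' SNP sites are stored as a width-1 \link[GenomicRanges]{GRanges} (1-based)
#' whose metadata columns carry the raw allele depths and the derived B-allele
#' frequencies in the matched non-tumor (`NT`) and tumor (`T`) samples. The
#' BAF is alt/(ref+alt) and is `NA` where total depth is zero.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param refNT,altNT Non-negative reference/alternate read counts in the
#'   non-tumor sample.
#' @param refT,altT Read counts in the tumor sample.
#' @param ref,alt Optional allele bases; kept as labels for downstream
#'   phasing tables, never interpreted.
#' @return A `GRanges` with metadata columns `refNT`, `altNT`, `refT`, `altT`,
#'   `bafNT`, `bafT` (and `ref`/`alt` when given).
#' @examples
#' snpSites("chr11", c(100, 200), refNT = c(10, 12), altNT = c(10, 9),
#'          refT = c(2, 30), altT = c(28, 3))
#' @export
snpSites <- function(chrom, pos, refNT, altNT, refT, altT,
                     ref = NULL, alt = NULL) {
  counts <- list(refNT = refNT, altNT = altNT, refT = refT, altT = altT)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (any(is.na(v)) || any(v < 0))
      stop(sprintf("'%s' must be non-negative read counts", nm))
  }
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$refNT <- as.integer(refNT)
  mcols(gr)$altNT <- as.integer(altNT)
  mcols(gr)$refT <- as.integer(refT)
  mcols(gr)$altT <- as.integer(altT)
  mcols(gr)$bafNT <- computeBaf(refNT, altNT)
  mcols(gr)$bafT <- computeBaf(refT, altT)
  if (!is.null(ref)) mcols(gr)$ref <- as.character(ref)
  if (!is.null(alt)) mcols(gr)$alt <- as.character(alt)
  gr
}

## Checks that a GRanges carries the SNP-site metadata columns.
.assertSnpSites <- function(sites) {
  needed <- c("refNT", "altNT", "refT", "altT", "bafNT", "bafT")
  missing <- setdiff(needed, colnames(mcols(sites)))
  if (length(missing))
    stop("not a SNP-site GRanges; missing metadata columns: ",
         paste(missing, collapse = ", "))
  invisible(sites)
}
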