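test_that("assignParentalAlleles phases heterozygous SNPs by the tumor disequilibrium", {
  sites <- snpSites("chr11", c(100, 200, 300),
                    refNT = c(10, 10, 39), altNT = c(10, 10, 1),
                    refT = c(1, 19, 1), altT = c(19, 1, 19),
                    ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  phased <- assignParentalAlleles(sites, testLocus())
  ## site 3 (NT BAF 0.025) is homozygous and excluded
  expect_equal(GenomicRanges::start(phased), c(100, 200))
  expect_equal(S4Vectors::mcols(phased)$patAllele, c("T", "C"))
  expect_equal(S4Vectors::mcols(phased)$matAllele, c("A", "G"))

  hom <- snpSites("chr11", 400, refNT = 39, altNT = 1, refT = 1, altT = 19)
  expect_error(assignParentalAlleles(hom, testLocus()), "no phasable")
})

test_that("aggregateCellCounts sums PAT/MAT reads per cell following the phasing", {
  phased <- data.frame(chrom = "chr11", pos = c(100, 200, 300),
                       pat_allele = c("A", "alt", "ref"),
                       mat_allele = c("T", "ref", "alt"))
  counts <- data.frame(
    cell_id = c("c1", "c1", "c1", "c2", "c3"),
    chrom = "chr11",
    pos = c(100, 200, 300, 100, 999),
    allele = c("A", "alt", "alt", "T", "A"),
    count = c(3, 2, 1, 4, 7))
  expect_message(cells <- aggregateCellCounts(counts, phased), "dropped 7")
  c1 <- cells[cells$cell_id == "c1", ]
  expect_equal(c(c1$pat_reads, c1$mat_reads), c(5L, 1L))
  expect_equal(c1$baf_cell, 5 / 6)
  ## PAT on ref at one SNP and alt at another: counts follow the phasing
  c2 <- cells[cells$cell_id == "c2", ]
  expect_equal(c(c2$pat_reads, c2$mat_reads), c(0L, 4L))
  ## a cell with all reads unphased has no BAF
  c3 <- cells[cells$cell_id == "c3", ]
  expect_true(is.na(c3$baf_cell))

  ## invariant to row-order permutation of the count table
  set.seed(1)
  perm <- counts[sample.int(nrow(counts)), ]
  cellsPerm <- suppressMessages(aggregateCellCounts(perm, phased))
  expect_equal(cells[order(cells$cell_id), ],
               cellsPerm[order(cellsPerm$cell_id), ],
               ignore_attr = TRUE)
})

test_that("callCell applies the 8-read / 85% / 60% three-way rule", {
  expect_equal(callCell(10, 0), "cn_LOH")
  expect_equal(callCell(4, 4), "no_cnLOH")
  expect_equal(callCell(7, 2), "unknown")   # BAF 0.78, between bounds
  expect_equal(callCell(5, 2), "unknown")   # 7 reads < 8
  ## boundaries are inclusive
  expect_equal(callCell(17, 3), "cn_LOH")   # BAF exactly 0.85
  expect_equal(callCell(6, 4), "no_cnLOH")  # BAF exactly 0.60
  expect_error(callCell(1, 1, lohBaf = 0.5, refBaf = 0.6), "below")
})

test_that("callCell agrees with the literal rule on every (PAT, MAT) pair up to 20 reads", {
  grid <- expand.grid(pat = 0:20, mat = 0:20)
  grid <- grid[grid$pat + grid$mat <= 20, ]
  got <- callCell(grid$pat, grid$mat)
  want <- mapply(oracleCallCell, grid$pat, grid$mat)
  expect_equal(got, unname(want))
})

test_that("annotateReferenceSample forces no_cnLOH for unaltered samples", {
  cells <- data.frame(cell_id = c("c1", "c2"), pat_reads = c(9L, 0L),
                      mat_reads = c(0L, 9L), baf_cell = c(1, 0))
  unalt <- annotateReferenceSample(cells, sampleIsAltered = FALSE)
  expect_equal(unalt$call, c("no_cnLOH", "no_cnLOH"))
  alt <- annotateReferenceSample(cells, sampleIsAltered = TRUE)
  expect_equal(alt$call, c("cn_LOH", "no_cnLOH"))
  empty <- annotateReferenceSample(cells[0, ], sampleIsAltered = FALSE)
  expect_equal(nrow(empty), 0L)
})

test_that("summarizeByCellType reports per-type BAF and cn-LOH fractions with unknowns counted", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    pat_reads = c(10L, 10L, 5L, 0L, 2L, 1L),
    mat_reads = c(0L, 0L, 5L, 10L, 1L, 1L),
    baf_cell = c(1, 1, 0.5, 0, 2 / 3, 0.5),
    cell_type = c("hepatocyte", "hepatocyte", "hepatocyte", "hepatocyte",
                  "kupffer", "kupffer"))
  cells <- annotateReferenceSample(cells, TRUE)
  s <- summarizeByCellType(cells)
  hep <- s[s$cell_type == "hepatocyte", ]
  expect_equal(hep$n_cells, 4L)
  expect_equal(hep$frac_cnloh, 0.5)   # 2 cn_LOH / 4 determinate
  expect_equal(hep$mean_baf, mean(c(1, 1, 0.5, 0)))
  ## all-unknown type: fraction 0 by convention, unknowns reported
  kup <- s[s$cell_type == "kupffer", ]
  expect_equal(kup$n_unknown, 2L)
  expect_equal(kup$frac_cnloh, 0)
})

test_that("error-free LOH cells are always called once depth suffices", {
  sim <- simulateCells(rho = 1, nCells = 50, readsPerCellMean = 15,
                       errorRate = 0, seed = 11)
  cells <- aggregateCellCounts(sim$counts, sim$phased)
  expect_true(all(cells$baf_cell == 1))
  calls <- callCell(cells$pat_reads, cells$mat_reads)
  enough <- cells$pat_reads + cells$mat_reads >= 8
  expect_true(all(calls[enough] == "cn_LOH"))
})

test_that("calls are invariant to SNP relabeling", {
  sim <- simulateCells(rho = 0.5, nCells = 100, seed = 3)
  cells <- aggregateCellCounts(sim$counts, sim$phased)
  ## relabel SNP positions consistently in both tables
  shift <- function(d) transform(d, pos = pos + 7)
  cells2 <- aggregateCellCounts(shift(sim$counts), shift(sim$phased))
  expect_equal(cells$pat_reads, cells2$pat_reads)
  expect_equal(callCell(cells$pat_reads, cells$mat_reads),
               callCell(cells2$pat_reads, cells2$mat_reads))
})
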