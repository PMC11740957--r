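makeCountSE <- function(counts, indication = NULL, source = NULL) {
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(indication)) cd$indication <- indication
  if (!is.null(source)) cd$source <- source
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
}

randCounts <- function(nGenes, nSamples, genes = NULL, lambda = 50) {
  m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples)
  rownames(m) <- if (is.null(genes)) sprintf("g%03d", seq_len(nGenes)) else genes
  colnames(m) <- sprintf("s%02d", seq_len(nSamples))
  m
}

test_that("intersectGenes subsets to the sorted common gene set", {
  set.seed(1)
  m1 <- randCounts(3, 2, genes = c("A", "B", "C"))
  m2 <- randCounts(3, 4, genes = c("D", "C", "B"))
  out <- intersectGenes(list(m1, m2))
  expect_identical(rownames(out[[1]]), c("B", "C"))
  expect_identical(rownames(out[[2]]), c("B", "C"))
  expect_identical(out[[1]]["B", ], m1["B", ])
  expect_identical(out[[2]]["C", ], m2["C", ])

  # single input: unchanged content, genes sorted
  m3 <- randCounts(4, 2, genes = c("z", "m", "a", "k"))
  out1 <- intersectGenes(list(m3))
  expect_identical(rownames(out1[[1]]), sort(rownames(m3)))
  expect_identical(out1[[1]], m3[sort(rownames(m3)), ])
})

test_that("intersectGenes matches a brute-force set intersection", {
  set.seed(42)
  universe <- sprintf("gene%04d", 1:500)
  shared <- sample(universe, 20)
  sets <- lapply(1:3, function(i)
    union(shared, sample(setdiff(universe, shared), 30)))
  mats <- lapply(sets, function(g) randCounts(length(g), 3, genes = sample(g)))
  out <- intersectGenes(mats)
  brute <- sort(Reduce(intersect, lapply(mats, rownames)))
  expect_identical(rownames(out[[1]]), brute)
  expect_length(brute, 20L)
})

test_that("intersectGenes is idempotent and order-independent", {
  set.seed(7)
  mats <- lapply(1:3, function(i)
    randCounts(30, 2, genes = sample(sprintf("g%03d", 1:60), 30)))
  out <- intersectGenes(mats)
  again <- intersectGenes(out)
  expect_identical(lapply(again, rownames), lapply(out, rownames))
  perm <- intersectGenes(mats[c(3, 1, 2)])
  expect_identical(rownames(perm[[1]]), rownames(out[[1]]))
  expect_error(
    intersectGenes(list(randCounts(3, 2, genes = c("A", "B", "C")),
                        randCounts(2, 2, genes = c("X", "Y")))),
    "disjoint")
})

test_that("filterSmallIndications applies the minimum-samples rule", {
  set.seed(3)
  counts <- randCounts(10, 14)
  se <- makeCountSE(counts, indication = rep(c("LUAD", "BRCA"), c(10, 4)))
  kept <- filterSmallIndications(se, minSamples = 5)
  expect_identical(unique(kept$indication), "LUAD")
  expect_identical(ncol(kept), 10L)
  expect_identical(ncol(filterSmallIndications(se, minSamples = 1)), 14L)
  expect_error(filterSmallIndications(se, minSamples = 100), "no samples")
})

test_that("filterSmallIndications matches a brute-force tally and keeps NAs", {
  set.seed(9)
  n <- 100
  ind <- sample(c(paste0("I", 1:6), NA), n, replace = TRUE,
                prob = c(0.30, 0.22, 0.15, 0.10, 0.06, 0.02, 0.15))
  se <- makeCountSE(randCounts(5, n), indication = ind)
  kept <- filterSmallIndications(se, minSamples = 5)
  tab <- table(ind, useNA = "no")
  expected <- sum(tab[tab >= 5]) + sum(is.na(ind))
  expect_identical(ncol(kept), as.integer(expected))
  expect_identical(sum(is.na(kept$indication)), sum(is.na(ind)))
})

test_that("tmmFactors: identical columns give factors of exactly 1", {
  set.seed(5)
  x <- randCounts(100, 1)
  counts <- x[, rep(1, 4)]
  colnames(counts) <- paste0("s", 1:4)
  expect_equal(unname(tmmFactors(counts)), rep(1, 4))
})

test_that("tmmFactors is invariant to a global rescaling of all counts", {
  set.seed(6)
  counts <- randCounts(150, 5, lambda = 80)
  expect_equal(tmmFactors(counts), tmmFactors(counts * 2L), tolerance = 1e-12)
})

test_that("tmmFactors matches the from-definition TMM oracle", {
  set.seed(8)
  counts <- randCounts(200, 4, lambda = 60)
  counts[order(-rowSums(counts))[1:5], 2] <-
    counts[order(-rowSums(counts))[1:5], 2] * 10L
  f <- tmmFactors(counts)
  expect_equal(unname(f), unname(oracleTMM(counts)), tolerance = 1e-6)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  zero <- counts; zero[, 3] <- 0L
  expect_error(tmmFactors(zero), "zero library size")
})

test_that("logCPM implements log2(CPM + 1) with TMM-adjusted library sizes", {
  set.seed(10)
  counts <- randCounts(100, 10, lambda = 30)
  f <- tmmFactors(counts)
  vals <- logCPM(counts, f)
  eff <- colSums(counts) * f
  direct <- log2(sweep(counts, 2, eff, "/") * 1e6 + 1)
  expect_equal(unname(vals[, ]), unname(direct), tolerance = 1e-12)
  expect_true(all(vals >= 0))
  # a zero count maps to exactly 0
  counts[1, 1] <- 0L
  expect_identical(logCPM(counts, f)[1, 1], 0)
  # unit CPM maps to exactly 1: a single count at effective library size 1e6
  one <- matrix(c(1L, 999999L, 1L, 999999L), 2, 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(logCPM(one, c(1, 1))["g1", "a"], 1)
  expect_error(logCPM(counts, c(-1, f[-1])), "positive")
})

test_that("logCPM is monotone in the count for a fixed sample", {
  set.seed(11)
  counts <- randCounts(50, 3)
  vals <- logCPM(counts, rep(1, 3))
  for (j in 1:3) {
    ord <- order(counts[, j])
    expect_true(all(diff(vals[ord, j]) >= 0))
  }
})

test_that("count/metadata TSV round trip preserves the data", {
  set.seed(12)
  counts <- randCounts(20, 6)
  dir <- withr::local_tempdir()
  cf <- file.path(dir, "counts.tsv")
  mf <- file.path(dir, "meta.tsv")
  writeMatrixTSV(counts, cf, assay = NULL)
  write.table(data.frame(sample_id = colnames(counts),
                         source = rep(c("A", "B"), 3),
                         indication = rep(c("x", "y", NA), 2)),
              mf, sep = "\t", quote = FALSE, row.names = FALSE)
  se <- readCounts(cf, mf)
  expect_equal(unname(as.matrix(SummarizedExperiment::assay(se, "counts"))),
               unname(counts))
  expect_identical(rownames(se), rownames(counts))
  expect_identical(as.character(se$source), rep(c("A", "B"), 3))
  norm <- logCPM(se)
  expect_true("logcpm" %in% SummarizedExperiment::assayNames(norm))
  expect_equal(length(norm$tmm), 6L)
})
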