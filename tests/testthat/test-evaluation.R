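test_that("pcaEmbed fits on the reference and transforms queries consistently", {
  set.seed(71)
  ref <- matrix(rnorm(40 * 12), 40, 12)
  emb <- pcaEmbed(ref, queries = ref, nComponents = 12L)
  expect_equal(emb$queries, unname(emb$reference), ignore_attr = TRUE)
  # orthogonal transform identity: all components reconstruct centered data
  recon <- emb$reference %*% t(emb$rotation)
  expect_equal(recon, unname(sweep(ref, 2, emb$center)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalue ordering: successive component variances are non-increasing
  vars <- apply(emb$reference, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  expect_error(pcaEmbed(ref, nComponents = 50L), "exceeds")
})

test_that("nnClassify handles degenerate k and separable clusters", {
  set.seed(72)
  ref <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
               matrix(rnorm(60, 8, 0.3), 30, 2))
  labs <- rep(c("A", "B"), each = 30)
  q <- matrix(rnorm(20, 0, 0.3), 10, 2)
  cls1 <- nnClassify(q, ref, labs, k = 1L)
  nn1 <- apply(q, 1, function(p)
    labs[which.min(colSums((t(ref) - p)^2))])
  expect_identical(cls1$assigned, nn1)
  cls25 <- nnClassify(q, ref, labs, k = 25L)
  expect_identical(cls25$assigned, rep("A", 10))
  expect_identical(dim(cls25$neighborLabels), c(10L, 25L))
  # the assigned label is always among the neighbor labels
  expect_true(all(vapply(1:10, function(i)
    cls25$assigned[i] %in% cls25$neighborLabels[i, ], logical(1))))
  expect_error(nnClassify(q, ref[0, ], character(0), k = 1L), "empty")
  expect_error(nnClassify(q, ref, labs, k = 100L), "exceeds")
})

test_that("nnClassify matches the exhaustive brute-force oracle, ties included", {
  set.seed(73)
  for (i in 1:10) {
    nr <- sample(20:60, 1)
    d <- sample(2:5, 1)
    ref <- matrix(round(rnorm(nr * d), 1), nr, d)  # rounding induces ties
    labs <- sample(c("x", "y", "z"), nr, replace = TRUE)
    q <- matrix(round(rnorm(8 * d), 1), 8, d)
    k <- sample(c(2L, 4L, 25L), 1)
    k <- min(k, nr)
    expect_identical(nnClassify(q, ref, labs, k)$assigned,
                     oracleKNN(q, ref, labs, k))
  }
  # explicit even-vote tie: 2 neighbors each; broken by summed distance
  ref <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), 4, 2, byrow = TRUE)
  labs <- c("b", "b", "a", "a")
  cls <- nnClassify(matrix(c(2, 2), 1, 2), ref, labs, k = 4L)
  expect_identical(cls$assigned, "b")
  expect_identical(cls$assigned, oracleKNN(matrix(c(2, 2), 1, 2), ref, labs, 4L))
})

test_that("agreementRate scores annotated queries and reports exclusions", {
  set.seed(74)
  ref <- matrix(rnorm(40), 20, 2)
  labs <- rep(c("A", "B"), 10)
  cls <- nnClassify(ref, ref, labs, k = 1L)
  allAgree <- agreementRate(cls, labs)
  expect_equal(allAgree$rate, 1.0)
  noneAnnot <- agreementRate(cls, rep(NA_character_, 20))
  expect_true(is.na(noneAnnot$rate))
  expect_identical(noneAnnot$nExcluded, 20L)
  # random annotations over 4 classes agree at ~1/4
  set.seed(75)
  n <- 400L
  q <- matrix(rnorm(n * 3), n, 3)
  refLabs <- sample(paste0("c", 1:4), n, replace = TRUE)
  cls2 <- nnClassify(q, matrix(rnorm(n * 3), n, 3), refLabs, k = 5L)
  rate <- agreementRate(cls2, sample(paste0("c", 1:4), n, replace = TRUE))$rate
  expect_lt(abs(rate - 0.25), 3 * sqrt(0.25 * 0.75 / n) + 0.02)
})

test_that("differentialExpression agrees with the t.test oracle and BH rules", {
  set.seed(76)
  a <- matrix(rnorm(15 * 40), 15, 40); colnames(a) <- sprintf("g%02d", 1:40)
  b <- matrix(rnorm(12 * 40, 0.4), 12, 40); colnames(b) <- colnames(a)
  de <- differentialExpression(a, b, alpha = 0.05)
  orc <- oracleWelch(a, b)
  expect_equal(de$stats$t, unname(orc[, "t"]), tolerance = 1e-10)
  expect_equal(de$stats$p, unname(orc[, "p"]), tolerance = 1e-10)
  expect_equal(de$stats$lfc, unname(colMeans(a) - colMeans(b)))
  # BH adjusted p-values: monotone in raw-p rank, bounded by 1
  ordp <- order(de$stats$p)
  expect_true(all(diff(de$stats$padj[ordp]) >= -1e-12))
  expect_true(all(de$stats$padj <= 1))
})

test_that("differentialExpression null self-comparison passes nothing and
           zero-variance genes are flagged", {
  set.seed(77)
  a <- matrix(rnorm(10 * 30), 10, 30)
  de <- differentialExpression(a, a, alpha = 0.01)
  expect_identical(nrow(de$top), 0L)
  expect_true(all(de$stats$p == 1 | de$stats$t == 0))
  const <- cbind(a, 5)  # last gene constant in both groups
  de2 <- differentialExpression(const, const + 0 * const, alpha = 0.01)
  expect_true(de2$stats$zeroVar[31])
  expect_identical(de2$stats$p[31], 1)
})

test_that("spiked simulation: shifted genes pass and outrank nulls", {
  set.seed(78)
  hits <- 0L
  for (s in 1:2) {
    a <- matrix(rnorm(30 * 500), 30, 500)
    b <- matrix(rnorm(30 * 500), 30, 500)
    b[, 1:20] <- b[, 1:20] + 2
    colnames(a) <- colnames(b) <- sprintf("g%03d", 1:500)
    de <- differentialExpression(b, a, alpha = 0.01, topN = 100L)
    spiked <- sprintf("g%03d", 1:20)
    passed <- de$stats$gene[de$stats$passes]
    rankedAbove <- all(head(de$top$gene, 20) %in% spiked)
    if (all(spiked %in% passed) && rankedAbove) hits <- hits + 1L
  }
  expect_identical(hits, 2L)
})

test_that("batchMixingEntropy separates mixed from pure neighborhoods", {
  set.seed(79)
  mixed <- matrix(rnorm(200 * 2), 200, 2)
  labsM <- rep(c("A", "B"), 100)
  entM <- batchMixingEntropy(mixed, labsM, k = 20L)
  expect_gt(entM$mean, 0.85)
  apart <- rbind(matrix(rnorm(100 * 2, 0, 0.2), 100, 2),
                 matrix(rnorm(100 * 2, 50, 0.2), 100, 2))
  labsS <- rep(c("A", "B"), each = 100)
  expect_equal(batchMixingEntropy(apart, labsS, k = 20L)$mean, 0)
  expect_error(batchMixingEntropy(mixed, rep("A", 200), k = 20L),
               "at least 2 sources")
})

test_that("report writers emit the documented TSV columns", {
  set.seed(80)
  ref <- matrix(rnorm(60), 30, 2)
  labs <- rep(c("A", "B", "C"), 10)
  q <- matrix(rnorm(10), 5, 2)
  rownames(q) <- paste0("q", 1:5)
  cls <- nnClassify(q, ref, labs, k = 5L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeClassificationTSV(cls, c("A", "B", NA, "C", "A"), f1)
  rep1 <- read.delim(f1)
  expect_identical(colnames(rep1), c("sample_id", "annotated_label",
                                     "assigned_label", "vote_count",
                                     "agreement"))
  expect_identical(nrow(rep1), 5L)
  a <- matrix(rnorm(5 * 8), 5, 8); b <- matrix(rnorm(5 * 8), 5, 8)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeDETableTSV(differentialExpression(a, b), f2)
  rep2 <- read.delim(f2)
  expect_identical(colnames(rep2), c("gene", "lfc", "t", "p", "p_adj",
                                     "passes"))
})
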