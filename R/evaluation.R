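#' PCA embedding fitted on a reference set
#'
#' Principal components are fitted on the reference matrix (mean-centered,
#' no per-gene scaling); query samples are transformed with the reference's
#' centering and loadings, avoiding query-set leakage into the fit.
#'
#' @param reference samples x genes matrix the components are fitted on.
#' @param queries optional samples x genes matrix on the same gene space.
#' @param nComponents number of components (default 70).
#' @return list with `reference` and `queries` coordinate matrices
#'   (samples x nComponents), plus `rotation`, `center` and `sdev`.
#' @export
pcaEmbed <- function(reference, queries = NULL, nComponents = 70L) {
  reference <- as.matrix(reference)
  maxComp <- min(dim(reference))
  if (nComponents > maxComp)
    stop(sprintf("nComponents = %d exceeds min(dim(reference)) = %d",
                 nComponents, maxComp))
  pr <- prcomp(reference, center = TRUE, scale. = FALSE, rank. = nComponents)
  qc <- NULL
  if (!is.null(queries)) {
    queries <- as.matrix(queries)
    stopifnot(ncol(queries) == ncol(reference))
    qc <- sweep(queries, 2L, pr$center) %*% pr$rotation
  }
  list(reference = pr$x, queries = qc, rotation = pr$rotation,
       center = pr$center, sdev = pr$sdev)
}

.pairwiseDist2 <- function(a, b) {
  # squared Euclidean distances, rows of a vs rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Nearest-neighbor label assignment
#'
#' For each query, finds its k nearest reference points by Euclidean
#' distance and assigns the majority label among them. Vote ties are broken
#' by the smaller summed distance to the tied label's neighbors, then by
#' lexicographic label order; equal distances rank by reference index.
#'
#' @param queries,reference coordinate matrices (e.g. from [pcaEmbed()]).
#' @param refLabels character labels, one per reference row.
#' @param k neighborhood size (default 25).
#' @return object of class `NeighborClassification`: list with `assigned`
#'   (character, per query), `neighborLabels` (queries x k character
#'   matrix), `neighborIndex`, `voteCounts` (list of named vote tables) and
#'   `k`.
#' @export
nnClassify <- function(queries, reference, refLabels, k = 25L) {
  queries <- as.matrix(queries); reference <- as.matrix(reference)
  if (nrow(reference) == 0L) stop("reference set is empty")
  refLabels <- as.character(refLabels)
  stopifnot(length(refLabels) == nrow(reference), ncol(queries) == ncol(reference))
  if (k > nrow(reference))
    stop(sprintf("k = %d exceeds reference size %d", k, nrow(reference)))
  d2 <- .pairwiseDist2(queries, reference)
  nq <- nrow(queries)
  assigned <- character(nq)
  nbrLab <- matrix(NA_character_, nq, k)
  nbrIdx <- matrix(NA_integer_, nq, k)
  votes <- vector("list", nq)
  for (i in seq_len(nq)) {
    ord <- order(d2[i, ])[seq_len(k)]
    labs <- refLabels[ord]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(l) sum(sqrt(d2[i, ord[labs == l]])),
                     numeric(1))
      top <- top[sums == min(sums)]
      top <- sort(top)[1L]
    }
    assigned[i] <- top
    nbrLab[i, ] <- labs
    nbrIdx[i, ] <- ord
    votes[[i]] <- tab
  }
  structure(list(assigned = assigned, neighborLabels = nbrLab,
                 neighborIndex = nbrIdx, voteCounts = votes, k = k,
                 queryIds = rownames(queries)),
            class = "NeighborClassification")
}

#' @export
print.NeighborClassification <- function(x, ...) {
  cat(sprintf("NeighborClassification: %d queries, k = %d\n",
              length(x$assigned), x$k))
  print(table(x$assigned))
  invisible(x)
}

#' Agreement between assigned and annotated labels
#'
#' @param classification a [nnClassify()] result.
#' @param annotations character vector of annotated labels per query; NA
#'   marks unannotated queries, which are excluded from the denominator and
#'   counted separately.
#' @return list with `rate` (fraction agreeing, NA when no query is
#'   annotated), `nScored`, `nExcluded` and the per-query `agreement`
#'   logical vector.
#' @export
agreementRate <- function(classification, annotations) {
  stopifnot(inherits(classification, "NeighborClassification"))
  annotations <- as.character(annotations)
  stopifnot(length(annotations) == length(classification$assigned))
  scored <- !is.na(annotations)
  agree <- ifelse(scored, classification$assigned == annotations, NA)
  list(rate = if (any(scored)) mean(agree[scored]) else NA_real_,
       nScored = sum(scored), nExcluded = sum(!scored),
       agreement = agree)
}

#' Differential expression between two groups (Welch t-test + BH)
#'
#' Per gene on log-space values: mean difference (log2 fold change), Welch
#' two-sample t statistic, raw and Benjamini-Hochberg adjusted p-values.
#' Genes with zero variance in both groups are flagged and given p = 1.
#' The reported `top` table contains the genes with adjusted p below
#' `alpha`, ranked by absolute fold change and truncated to `topN`.
#'
#' @param groupA,groupB samples x genes matrices on the same gene space,
#'   each with >= 2 samples.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param topN maximum genes in the ranked table (default 100).
#' @param varEqual use Student's pooled-variance t instead of Welch.
#' @return list with `stats` (data.frame over all genes: gene, lfc, t, df,
#'   p, padj, zeroVar, passes) and `top` (the ranked passing subset).
#' @export
differentialExpression <- function(groupA, groupB, alpha = 0.01,
                                   topN = 100L, varEqual = FALSE) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(ncol(groupA) == ncol(groupB), nrow(groupA) >= 2L,
            nrow(groupB) >= 2L)
  nA <- nrow(groupA); nB <- nrow(groupB)
  mA <- colMeans(groupA); mB <- colMeans(groupB)
  vA <- colSums(sweep(groupA, 2L, mA)^2) / (nA - 1)
  vB <- colSums(sweep(groupB, 2L, mB)^2) / (nB - 1)
  lfc <- mA - mB
  if (varEqual) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(lfc))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  tstat <- lfc / se
  p <- 2 * pt(-abs(tstat), df)
  zeroVar <- vA == 0 & vB == 0
  tstat[zeroVar] <- NA_real_
  df[zeroVar] <- NA_real_
  p[zeroVar] <- 1
  padj <- p.adjust(p, method = "BH")
  genes <- colnames(groupA)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_along(lfc))
  stats <- data.frame(gene = genes, lfc = lfc, t = tstat, df = df, p = p,
                      padj = padj, zeroVar = zeroVar,
                      passes = padj < alpha, row.names = NULL)
  top <- stats[stats$passes, , drop = FALSE]
  top <- top[order(-abs(top$lfc), top$gene), , drop = FALSE]
  top <- head(top, topN)
  rownames(top) <- NULL
  list(stats = stats, top = top)
}

#' Batch-mixing entropy of local neighborhoods
#'
#' For each sample, the Shannon entropy of the source composition among its
#' k nearest neighbors (self excluded), normalized by ln K so 1 means
#' perfectly intermixed sources and 0 means pure single-source
#' neighborhoods.
#'
#' @param coords samples x dims coordinate matrix.
#' @param labels per-sample source labels (at least 2 distinct).
#' @param k neighborhood size (default 25).
#' @return list with `perSample` entropies and their `mean`.
#' @export
batchMixingEntropy <- function(coords, labels, k = 25L) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(coords), k >= 2L)
  K <- length(unique(labels))
  if (K < 2L) stop("batch-mixing entropy needs at least 2 sources")
  if (k >= nrow(coords)) stop("k must be below the number of samples")
  d2 <- .pairwiseDist2(coords, coords)
  diag(d2) <- Inf
  ent <- vapply(seq_len(nrow(coords)), function(i) {
    nb <- labels[order(d2[i, ])[seq_len(k)]]
    pr <- table(nb) / k
    -sum(pr * log(pr)) / log(K)
  }, numeric(1))
  list(perSample = ent, mean = mean(ent))
}

#' k-NN probe accuracy for a label on an embedding
#'
#' Diagnostic used to quantify how much source (or cluster) information an
#' embedding retains: a fresh k-nearest-neighbor classifier is trained on a
#' deterministic half of the samples (every other one) and scored on the
#' held-out half via [nnClassify()].
#'
#' @param x samples x dims matrix (log-CPM, latent codes, PCA coords, ...).
#' @param labels per-sample labels to probe for.
#' @param k neighbors (default 5).
#' @return held-out classification accuracy in \[0, 1\].
#' @export
knnProbeAccuracy <- function(x, labels, k = 5L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  train <- seq_len(nrow(x)) %% 2L == 1L
  cls <- nnClassify(x[!train, , drop = FALSE], x[train, , drop = FALSE],
                    labels[train], k = k)
  mean(cls$assigned == labels[!train])
}

#' Write a neighbor-classification report as TSV
#'
#' Columns: sample_id, annotated_label, assigned_label, vote_count,
#' agreement.
#'
#' @param classification a [nnClassify()] result.
#' @param annotations annotated labels per query (NA allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClassificationTSV <- function(classification, annotations, path) {
  stopifnot(inherits(classification, "NeighborClassification"))
  ids <- classification$queryIds
  if (is.null(ids)) ids <- sprintf("query%04d", seq_along(classification$assigned))
  voteCount <- vapply(seq_along(classification$assigned), function(i)
    as.integer(classification$voteCounts[[i]][classification$assigned[i]]),
    integer(1))
  agr <- agreementRate(classification, annotations)
  write.table(data.frame(sample_id = ids, annotated_label = annotations,
                         assigned_label = classification$assigned,
                         vote_count = voteCount, agreement = agr$agreement),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassificationTSV
#' @param de a [differentialExpression()] result.
#' @export
writeDETableTSV <- function(de, path) {
  tab <- de$stats[, c("gene", "lfc", "t", "p", "padj", "passes")]
  names(tab) <- c("gene", "lfc", "t", "p", "p_adj", "passes")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
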