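#' Subset count matrices to their common gene set
#'
#' Restricts every matrix to the genes present in all of them, in a
#' deterministic lexicographic order, so independent runs over the same
#' datasets agree exactly. Sample content is unchanged. The caller supplies
#' gene universes (e.g. pre-filtered to protein-coding genes); no annotation
#' is done here.
#'
#' @param x a list of [SummarizedExperiment::SummarizedExperiment] objects
#'   (or count matrices) with gene identifiers as rownames.
#' @return a list of the same objects subset to the sorted common genes.
#' @export
intersectGenes <- function(x) {
  if (is(x, "SummarizedExperiment") || is.matrix(x)) x <- list(x)
  stopifnot(length(x) >= 1L)
  geneSets <- lapply(x, rownames)
  if (any(vapply(geneSets, is.null, logical(1))))
    stop("all inputs need gene identifiers as rownames")
  if (any(lengths(geneSets) == 0L)) stop("each input needs at least one gene")
  common <- Reduce(intersect, geneSets)
  if (length(common) == 0L) {
    for (i in seq_along(x)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(geneSets[[i]], geneSets[[j]])) == 0L)
          stop(sprintf("gene sets of inputs %d and %d are disjoint", j, i))
      }
    }
    stop("no gene is present in all inputs")
  }
  common <- sort(common)
  lapply(x, function(m) m[common, , drop = FALSE])
}

#' Drop samples from under-represented indications
#'
#' Removes all samples whose indication has fewer than `minSamples` samples,
#' mirroring the exclusion of indications with less than five samples.
#' Samples with a missing indication label are retained.
#'
#' @param x a [SummarizedExperiment::SummarizedExperiment] with an
#'   `indication` column in `colData` (NA allowed).
#' @param minSamples minimum samples an indication needs to be kept.
#' @return the filtered SummarizedExperiment.
#' @export
filterSmallIndications <- function(x, minSamples = 5L) {
  stopifnot(is(x, "SummarizedExperiment"), minSamples >= 1L)
  cd <- SummarizedExperiment::colData(x)
  if (!"indication" %in% colnames(cd))
    stop("colData must have an 'indication' column")
  ind <- as.character(cd$indication)
  tab <- table(ind, useNA = "no")
  keepInd <- names(tab)[tab >= minSamples]
  keep <- is.na(ind) | ind %in% keepInd
  if (!any(keep))
    stop("no samples left after removing indications with fewer than ",
         minSamples, " samples")
  x[, keep]
}

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    as.matrix(SummarizedExperiment::assay(x, "counts"))
  else as.matrix(x)
}

#' TMM scaling factors
#'
#' Between-sample normalization factors by the trimmed mean of M-values
#' method (computed with edgeR, the tool the procedure is defined by):
#' gene-wise log-ratios M and average log-abundances A against a reference
#' sample (the one whose upper quartile is closest to the mean upper
#' quartile), doubly trimmed (30% on M, 5% on A), then combined by a
#' precision-weighted mean. Factors are rescaled to geometric mean 1.
#'
#' @param x a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay, or a genes x samples count matrix.
#' @param logratioTrim,sumTrim trim fractions on M and A.
#' @return named positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
tmmFactors <- function(x, logratioTrim = 0.3, sumTrim = 0.05) {
  counts <- .countsOf(x)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  libs <- colSums(counts)
  if (any(libs <= 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[libs <= 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratioTrim,
                              sumTrim = sumTrim)
  names(f) <- colnames(counts)
  f
}

#' TMM-scaled log2 counts per million
#'
#' `value(g, s) = log2(count(g, s) / (libsize(s) * factor(s)) * 1e6 + 1)`:
#' counts per million on TMM-adjusted library sizes, with a pseudocount of 1
#' added to the CPM before the log, so a zero count maps to exactly 0 and
#' all values are non-negative.
#'
#' @param x a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay, or a genes x samples count matrix.
#' @param factors per-sample positive TMM factors; computed via
#'   [tmmFactors()] when NULL.
#' @return if `x` is a SummarizedExperiment, the same object with an added
#'   `logcpm` assay and a `tmm` column in `colData`; otherwise a genes x
#'   samples matrix of log2(CPM+1) values with the factors attached as
#'   attribute `"tmm"`. Use `t()` (or [moberFit()], which transposes
#'   internally) for the samples x genes orientation the model consumes.
#' @export
logCPM <- function(x, factors = NULL) {
  counts <- .countsOf(x)
  if (is.null(factors)) factors <- tmmFactors(x)
  if (length(factors) != ncol(counts))
    stop("need one TMM factor per sample")
  if (any(factors <= 0)) stop("TMM factors must be strictly positive")
  eff <- colSums(counts) * factors
  vals <- log2(sweep(counts, 2L, eff, "/") * 1e6 + 1)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "logcpm") <- vals
    x$tmm <- unname(factors)
    x
  } else {
    attr(vals, "tmm") <- factors
    vals
  }
}

#' Read a count matrix (genes as rows) with optional sample metadata
#'
#' Expects a delimited text file with gene identifiers in the first column
#' and a header row of sample identifiers; the optional metadata file is a
#' TSV with columns `sample_id`, `source` and optionally `indication`.
#'
#' @param countsFile path to the counts TSV/CSV (delimiter auto-detected
#'   from the extension).
#' @param metadataFile optional path to the sample metadata TSV.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay and any metadata columns in `colData`.
#' @export
readCounts <- function(countsFile, metadataFile = NULL) {
  sep <- if (grepl("\\.csv$", countsFile, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(countsFile, sep = sep, check.names = FALSE,
                   comment.char = "#")
  genes <- as.character(df[[1L]])
  counts <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(genes)) stop("duplicated gene identifiers in ", countsFile)
  if (any(counts < 0)) stop("negative counts in ", countsFile)
  rownames(counts) <- genes
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(metadataFile)) {
    md <- read.delim(metadataFile, sep = "\t", check.names = FALSE,
                     comment.char = "#")
    if (!"sample_id" %in% colnames(md))
      stop("metadata needs a 'sample_id' column")
    i <- match(colnames(counts), md$sample_id)
    if (anyNA(i))
      stop("metadata missing sample(s): ",
           paste(colnames(counts)[is.na(i)], collapse = ", "))
    for (col in setdiff(colnames(md), "sample_id")) cd[[col]] <- md[[col]][i]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
}

#' Write a matrix (or an assay) as a TSV with genes as rows
#'
#' @param x a matrix or SummarizedExperiment.
#' @param path output file.
#' @param assay assay to write when `x` is a SummarizedExperiment.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(x, path, assay = "logcpm") {
  m <- if (is(x, "SummarizedExperiment"))
    as.matrix(SummarizedExperiment::assay(x, assay)) else as.matrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @param factors named TMM factor vector from [tmmFactors()].
#' @export
writeTMMFactorsTSV <- function(factors, path) {
  write.table(data.frame(sample_id = names(factors), tmm_factor = factors),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
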