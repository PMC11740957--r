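#' Project expression profiles into another source's style
#'
#' Encodes each sample, then decodes its latent code with the one-hot source
#' vector swapped to `targetSource` — e.g. rendering cell-line profiles as if
#' they were clinical tumors. Sample count, gene count and ordering are
#' unchanged; outputs are non-negative log2(CPM+1)-scale values. Projecting a
#' sample to its own source is plain reconstruction (identical code path,
#' `s` unchanged).
#'
#' @param model a trained [MoberModel-class].
#' @param x normalized expression: samples x genes matrix, or a
#'   [SummarizedExperiment::SummarizedExperiment] with a `logcpm` assay
#'   (genes x samples). Gene identifiers must match `geneIds(model)` exactly.
#' @param targetSource name of the source to decode as; must be one of
#'   `sourceNames(model)`.
#' @param mode `"mean"` (default) decodes the posterior mean `mu` —
#'   deterministic, recommended for downstream analysis; `"sampled"` draws
#'   `z` via [reparameterize()] under `seed`.
#' @param seed seed used when `mode = "sampled"`.
#' @return same container as `x`: a samples x genes matrix, or the
#'   SummarizedExperiment with an added `projected` assay and projection
#'   provenance in `metadata()`.
#' @export
moberProject <- function(model, x, targetSource,
                         mode = c("mean", "sampled"), seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(is(model, "MoberModel"))
  if (!targetSource %in% model@sourceNames)
    stop("unknown target source '", targetSource, "'; registered sources: ",
         paste(model@sourceNames, collapse = ", "))
  isSE <- is(x, "SummarizedExperiment")
  mat <- if (isSE) t(SummarizedExperiment::assay(x, "logcpm")) else
    .asSampleMatrix(x, model@config$nGenes)
  gn <- colnames(mat)
  if (!is.null(gn) && !identical(gn, model@geneIds))
    stop("gene identifiers do not match the model's gene universe; ",
         "reorder/subset the input to geneIds(model)")
  code <- encode(model, mat)
  z <- if (mode == "mean") code$mu else {
    set.seed(seed)
    reparameterize(code$mu, code$logvar)
  }
  proj <- decode(model, z, rep(targetSource, nrow(mat)))
  rownames(proj) <- rownames(mat)
  if (isSE) {
    SummarizedExperiment::assay(x, "projected") <- t(proj)
    S4Vectors::metadata(x)$projection <-
      list(targetSource = targetSource, mode = mode,
           seed = if (mode == "sampled") seed else NA_integer_)
    x
  } else {
    proj
  }
}
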