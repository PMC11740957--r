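#' @import methods
#' @importFrom stats rnorm prcomp p.adjust pt var kmeans quantile rnbinom sd
#' @importFrom utils read.delim write.table head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MoberModel: an adversarial conditional variational autoencoder
#'
#' Container for the trained (or freshly initialized) model: encoder,
#' source-conditioned decoder and adversarial source discriminator, plus the
#' gene universe and the registered source names the one-hot conditioning
#' vector is defined over.
#'
#' @slot config list of architecture settings (see [moberModelConfig()]).
#' @slot params flat named list of weight matrices and bias vectors.
#' @slot sourceNames ordered character vector of the K registered sources;
#'   position i of the one-hot vector corresponds to `sourceNames[i]`.
#' @slot geneIds character vector of gene identifiers the model consumes,
#'   in the exact column order expected by [encode()].
#' @slot history data.frame of per-epoch loss components written by
#'   [moberFit()]; empty for an untrained model.
#'
#' @seealso [moberModel()], [moberFit()], [moberProject()]
#' @export
setClass("MoberModel",
  representation(
    config = "list",
    params = "list",
    sourceNames = "character",
    geneIds = "character",
    history = "data.frame"
  )
)

setValidity("MoberModel", function(object) {
  cfg <- object@config
  msg <- character()
  needed <- c("nGenes", "nSources", "latentDim",
              "encoderHidden", "decoderHidden", "adversaryHidden")
  if (!all(needed %in% names(cfg)))
    msg <- c(msg, paste("config missing:",
                        paste(setdiff(needed, names(cfg)), collapse = ", ")))
  else {
    if (length(object@sourceNames) != cfg$nSources)
      msg <- c(msg, "length(sourceNames) must equal config$nSources")
    if (length(object@geneIds) != cfg$nGenes)
      msg <- c(msg, "length(geneIds) must equal config$nGenes")
    if (anyDuplicated(object@geneIds))
      msg <- c(msg, "geneIds must be unique")
    if (anyDuplicated(object@sourceNames))
      msg <- c(msg, "sourceNames must be unique")
    if (cfg$nSources < 2)
      msg <- c(msg, "at least two sources are required")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MoberModel-class compact description of architecture and
#'   training state.
#' @param object a `MoberModel`.
#' @export
setMethod("show", "MoberModel", function(object) {
  cfg <- object@config
  cat("MoberModel (adversarial conditional VAE)\n")
  cat(sprintf("  genes: %d | latent dim: %d | sources (K=%d): %s\n",
              cfg$nGenes, cfg$latentDim, cfg$nSources,
              paste(object@sourceNames, collapse = ", ")))
  cat(sprintf("  encoder: %s -> (mu, logvar)\n",
              paste(c(cfg$nGenes, cfg$encoderHidden), collapse = "-")))
  cat(sprintf("  decoder: [z+s] %s -> %d (ReLU)\n",
              paste(c(cfg$latentDim + cfg$nSources, cfg$decoderHidden),
                    collapse = "-"), cfg$nGenes))
  cat(sprintf("  adversary: %s -> %d (softmax)\n",
              paste(c(cfg$latentDim, cfg$adversaryHidden), collapse = "-"),
              cfg$nSources))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs | recon %.4g | adv acc %.3f\n",
                nrow(object@history), last$recon, last$advAcc))
  } else {
    cat("  untrained (freshly initialized weights)\n")
  }
  invisible(object)
})

#' @rdname MoberModel-class
#' @export
setGeneric("sourceNames", function(object) standardGeneric("sourceNames"))

#' @rdname MoberModel-class
#' @export
setMethod("sourceNames", "MoberModel", function(object) object@sourceNames)

#' @rdname MoberModel-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname MoberModel-class
#' @export
setMethod("geneIds", "MoberModel", function(object) object@geneIds)

#' @rdname MoberModel-class
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))

#' @rdname MoberModel-class
#' @export
setMethod("latentDim", "MoberModel", function(object) object@config$latentDim)

#' @rdname MoberModel-class
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @rdname MoberModel-class
#' @export
setMethod("trainingHistory", "MoberModel", function(object) object@history)

#' @rdname MoberModel-class
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname MoberModel-class
#' @export
setMethod("modelConfig", "MoberModel", function(object) object@config)
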