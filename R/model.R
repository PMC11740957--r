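#' Architecture configuration for a MoberModel
#'
#' The encoder runs the log2-CPM expression vector through SELU hidden layers
#' of 256, 128 and 64 nodes; linear heads on the last hidden layer emit the
#' posterior mean `mu` and log-variance `logvar` of the 64-dimensional latent
#' code. The decoder mirrors the encoder (64-128-256) and receives the one-hot
#' source vector `s` concatenated to the latent code at its first layer; its
#' output layer is ReLU so reconstructed log2(CPM+1) values are non-negative.
#' The adversary is a three-layer softmax classifier over the K sources that
#' reads the sampled latent code.
#'
#' @param nGenes number of genes (input/output dimension).
#' @param nSources number K of registered sources (K >= 2).
#' @param latentDim latent space dimension.
#' @param encoderHidden,decoderHidden,adversaryHidden integer vectors of
#'   hidden-layer widths. `decoderHidden` excludes the final output layer,
#'   `adversaryHidden` excludes the K-node softmax layer.
#' @return a validated list of class `moberModelConfig`.
#' @export
moberModelConfig <- function(nGenes, nSources, latentDim = 64L,
                             encoderHidden = c(256L, 128L, 64L),
                             decoderHidden = c(64L, 128L, 256L),
                             adversaryHidden = c(64L, 32L)) {
  cfg <- list(nGenes = as.integer(nGenes), nSources = as.integer(nSources),
              latentDim = as.integer(latentDim),
              encoderHidden = as.integer(encoderHidden),
              decoderHidden = as.integer(decoderHidden),
              adversaryHidden = as.integer(adversaryHidden))
  stopifnot(cfg$nGenes >= 1L, cfg$nSources >= 2L, cfg$latentDim >= 1L,
            all(cfg$encoderHidden > 0L), all(cfg$decoderHidden > 0L),
            all(cfg$adversaryHidden > 0L))
  class(cfg) <- c("moberModelConfig", "list")
  cfg
}

#' Create a freshly initialized MoberModel
#'
#' Weights are drawn LeCun-normal from the current RNG stream, so wrap the
#' call in `set.seed()` (or use [moberFit()], which seeds everything from its
#' training config) for reproducible initialization.
#'
#' @param geneIds character vector of gene identifiers, defining the input
#'   column order.
#' @param sourceNames ordered character vector of registered sources; the
#'   one-hot vector position i means `sourceNames[i]`.
#' @param config a [moberModelConfig()]; defaults are derived from
#'   `geneIds`/`sourceNames` lengths.
#' @return a [MoberModel-class] object.
#' @export
moberModel <- function(geneIds, sourceNames, config = NULL) {
  geneIds <- as.character(geneIds)
  sourceNames <- as.character(sourceNames)
  if (is.null(config))
    config <- moberModelConfig(length(geneIds), length(sourceNames))
  stopifnot(config$nGenes == length(geneIds),
            config$nSources == length(sourceNames))
  params <- .initParams(config)
  config <- unclass(config)
  new("MoberModel", config = config, params = params,
      sourceNames = sourceNames, geneIds = geneIds,
      history = .emptyHistory())
}

.emptyHistory <- function() {
  data.frame(epoch = integer(), recon = numeric(), kl = numeric(),
             advNLL = numeric(), lossVae = numeric(), lossMober = numeric(),
             advAcc = numeric())
}

.initParams <- function(cfg) {
  params <- list()
  # encoder trunk
  dims <- c(cfg$nGenes, cfg$encoderHidden)
  encNames <- .layerNames("enc", length(cfg$encoderHidden))
  for (i in seq_along(encNames)) {
    ly <- .initLayer(dims[i], dims[i + 1L])
    params[[paste0(encNames[i], ".W")]] <- ly$W
    params[[paste0(encNames[i], ".b")]] <- ly$b
  }
  hTop <- dims[length(dims)]
  for (head in c("mu", "lv")) {
    ly <- .initLayer(hTop, cfg$latentDim)
    params[[paste0(head, ".W")]] <- ly$W
    params[[paste0(head, ".b")]] <- ly$b
  }
  # decoder: [z, s] -> hidden -> nGenes (ReLU output)
  dims <- c(cfg$latentDim + cfg$nSources, cfg$decoderHidden, cfg$nGenes)
  decNames <- c(.layerNames("dec", length(cfg$decoderHidden)), "decout")
  for (i in seq_along(decNames)) {
    ly <- .initLayer(dims[i], dims[i + 1L])
    params[[paste0(decNames[i], ".W")]] <- ly$W
    params[[paste0(decNames[i], ".b")]] <- ly$b
  }
  # adversary: z -> hidden -> K logits
  dims <- c(cfg$latentDim, cfg$adversaryHidden, cfg$nSources)
  advNames <- c(.layerNames("adv", length(cfg$adversaryHidden)), "advout")
  for (i in seq_along(advNames)) {
    ly <- .initLayer(dims[i], dims[i + 1L])
    params[[paste0(advNames[i], ".W")]] <- ly$W
    params[[paste0(advNames[i], ".b")]] <- ly$b
  }
  params
}

.encNames <- function(cfg) .layerNames("enc", length(cfg$encoderHidden))
.decNames <- function(cfg) c(.layerNames("dec", length(cfg$decoderHidden)), "decout")
.advNames <- function(cfg) c(.layerNames("adv", length(cfg$adversaryHidden)), "advout")
.decActs <- function(cfg) c(rep("selu", length(cfg$decoderHidden)), "relu")
.advActs <- function(cfg) c(rep("selu", length(cfg$adversaryHidden)), "linear")

# logvar is clamped for numerical stability; the clamp mask is needed in the
# backward pass so gradients vanish where the clamp is active.
.LOGVAR_CLAMP <- 20

.asSampleMatrix <- function(x, nGenes, what = "x") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != nGenes)
    stop(sprintf("%s has %d columns; the model expects %d genes",
                 what, ncol(x), nGenes))
  x
}

.encodeForward <- function(params, cfg, x) {
  nms <- .encNames(cfg)
  ff <- .ffwd(.getLayers(params, nms), x, rep("selu", length(nms)))
  h <- ff$out
  mu <- .addBias(h %*% params[["mu.W"]], params[["mu.b"]])
  lvRaw <- .addBias(h %*% params[["lv.W"]], params[["lv.b"]])
  logvar <- pmin(pmax(lvRaw, -.LOGVAR_CLAMP), .LOGVAR_CLAMP)
  list(mu = mu, logvar = logvar, lvRaw = lvRaw, h = h, trunk = ff)
}

#' Encode expression profiles into the variational posterior
#'
#' Deterministic given the model weights: returns the per-sample posterior
#' mean and log-variance of the latent code, one row per sample.
#'
#' @param model a [MoberModel-class].
#' @param x numeric matrix of normalized expression, samples x genes (a single
#'   profile may be given as a vector). Columns must follow `geneIds(model)`.
#' @return list with matrices `mu` and `logvar` (samples x latentDim).
#' @seealso [reparameterize()], [decode()]
#' @export
encode <- function(model, x) {
  x <- .asSampleMatrix(x, model@config$nGenes)
  ff <- .encodeForward(model@params, model@config, x)
  list(mu = ff$mu, logvar = ff$logvar)
}

#' Sample a latent code by the reparameterization trick
#'
#' `z = mu + exp(logvar/2) * eps` with `eps ~ N(0, 1)` drawn from the current
#' RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param mu,logvar matrices (samples x latentDim) as returned by [encode()].
#' @return matrix `z` of the same shape.
#' @export
reparameterize <- function(mu, logvar) {
  stopifnot(all(dim(mu) == dim(logvar)))
  eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(logvar / 2) * eps
}

#' One-hot encode source labels
#'
#' @param sources character vector of source labels.
#' @param sourceNames ordered character vector of registered sources.
#' @return binary matrix, `length(sources)` x `length(sourceNames)`.
#' @export
oneHotSource <- function(sources, sourceNames) {
  idx <- match(as.character(sources), sourceNames)
  if (anyNA(idx))
    stop("unknown source(s): ",
         paste(unique(sources[is.na(idx)]), collapse = ", "),
         "; registered sources are: ", paste(sourceNames, collapse = ", "))
  s <- matrix(0, length(idx), length(sourceNames),
              dimnames = list(NULL, sourceNames))
  s[cbind(seq_along(idx), idx)] <- 1
  s
}

.checkOneHot <- function(s, K) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  s <- as.matrix(s)
  if (ncol(s) != K)
    stop(sprintf("one-hot matrix has %d columns; expected K = %d", ncol(s), K))
  ok <- apply(s, 1L, function(r) sum(r == 1) == 1 && sum(r == 0) == K - 1)
  if (!all(ok))
    stop("each conditioning row must be one-hot (a single 1, rest 0)")
  s
}

#' Decode latent codes conditioned on a source
#'
#' The one-hot source vector is concatenated to the latent code at the
#' decoder's first layer; the output layer is ReLU, so decoded log2(CPM+1)
#' profiles are non-negative. Swapping the source at decode time is what
#' projects a sample into another dataset's style (see [moberProject()]).
#' Implemented as a method on the `S4Vectors` `decode` generic so it
#' coexists with the rest of the Bioconductor stack in any load order.
#'
#' @param x a [MoberModel-class].
#' @param z latent matrix (samples x latentDim), or a single vector.
#' @param s either a character vector of source labels (recycled if length 1)
#'   or a one-hot matrix with `nSources` columns.
#' @return matrix of reconstructed expression, samples x genes.
#' @importFrom S4Vectors decode
#' @export
setMethod("decode", "MoberModel", function(x, z, s) {
  model <- x
  cfg <- model@config
  z <- .asSampleMatrix(z, cfg$latentDim, "z")
  if (is.character(s) || is.factor(s)) {
    s <- as.character(s)
    if (length(s) == 1L) s <- rep(s, nrow(z))
    s <- oneHotSource(s, model@sourceNames)
  } else {
    s <- .checkOneHot(s, cfg$nSources)
    if (nrow(s) == 1L && nrow(z) > 1L)
      s <- s[rep(1L, nrow(z)), , drop = FALSE]
  }
  stopifnot(nrow(s) == nrow(z))
  nms <- .decNames(cfg)
  ff <- .ffwd(.getLayers(model@params, nms), cbind(z, s), .decActs(cfg))
  out <- ff$out
  colnames(out) <- model@geneIds
  out
})

#' @importFrom S4Vectors decode
#' @export
S4Vectors::decode

#' Predict the source of latent codes (the adversary's view)
#'
#' @param model a [MoberModel-class].
#' @param z latent matrix (samples x latentDim), or a single vector.
#' @return matrix of class probabilities (samples x K), rows summing to 1,
#'   columns named by `sourceNames(model)`.
#' @export
discriminate <- function(model, z) {
  cfg <- model@config
  z <- .asSampleMatrix(z, cfg$latentDim, "z")
  nms <- .advNames(cfg)
  logits <- .ffwd(.getLayers(model@params, nms), z, .advActs(cfg))$out
  p <- .softmaxRows(logits)
  colnames(p) <- model@sourceNames
  p
}

#' Closed-form KL divergence of the diagonal-Gaussian posterior from N(0, I)
#'
#' `0.5 * sum_d(mu_d^2 + exp(logvar_d) - 1 - logvar_d)` per sample.
#'
#' @param mu,logvar matrices (samples x latentDim).
#' @return numeric vector, one non-negative value per sample.
#' @export
klDivergence <- function(mu, logvar) {
  stopifnot(all(dim(mu) == dim(logvar)))
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

#' VAE loss: reconstruction plus weighted KL regularization
#'
#' The reconstruction term is the negative log-likelihood of the input under
#' an isotropic Gaussian decoder on log2-CPM values, reported on a per-value
#' scale: the squared error averaged over genes and samples (additive
#' constants and the 1/2 dropped). Averaging rather than summing over genes
#' keeps the term on a scale commensurate with the default KL weight and
#' adversarial weight, independent of the gene universe size.
#' `lossVae = recon + wKL * kl`.
#'
#' @param x,xhat observed and reconstructed expression (samples x genes).
#' @param mu,logvar posterior parameters from [encode()].
#' @param wKL weight of the KL term.
#' @return list with `recon`, `kl`, `lossVae` (scalars).
#' @export
vaeLoss <- function(x, xhat, mu, logvar, wKL = 1.1e-5) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  stopifnot(all(dim(x) == dim(xhat)))
  recon <- mean((x - xhat)^2)
  kl <- mean(klDivergence(mu, logvar))
  list(recon = recon, kl = kl, lossVae = recon + wKL * kl)
}

#' Adversary negative log-likelihood
#'
#' Mean `-log p(true source | z)` over the batch; probabilities are clamped
#' at 1e-12 before the log so a confidently wrong adversary yields a large
#' finite loss.
#'
#' @param probs probability matrix from [discriminate()] (samples x K).
#' @param s true sources: a one-hot matrix, a character vector of labels
#'   (requires `sourceNames`), or integer class indices.
#' @param sourceNames registered sources, needed when `s` is character.
#' @return scalar mean negative log-likelihood.
#' @export
adversaryNLL <- function(probs, s, sourceNames = colnames(probs)) {
  probs <- as.matrix(probs)
  if (is.matrix(s)) {
    idx <- max.col(s, ties.method = "first")
  } else if (is.character(s) || is.factor(s)) {
    idx <- match(as.character(s), sourceNames)
    if (anyNA(idx)) stop("labels not in sourceNames")
  } else {
    idx <- as.integer(s)
  }
  stopifnot(length(idx) == nrow(probs), all(idx >= 1L), all(idx <= ncol(probs)))
  -mean(log(pmax(probs[cbind(seq_along(idx), idx)], 1e-12)))
}

#' Joint adversarial objective
#'
#' `lossMober = lossVae - lambdaAdv * advNLL`: the VAE is rewarded when the
#' adversary cannot recover the source from the latent code.
#'
#' @param lossVae,advNLL scalar loss components.
#' @param lambdaAdv adversarial weight (lambda).
#' @return scalar joint loss.
#' @export
moberLoss <- function(lossVae, advNLL, lambdaAdv = 0.11) {
  lossVae - lambdaAdv * advNLL
}
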