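#' Training configuration
#'
#' Defaults follow the MOBER reference training recipe: minibatch size 1600, Adam
#' with learning rate 1e-3, KL weight 1.1e-5 and adversarial weight 0.11.
#' The epoch budget is fixed (no early stopping); convergence is monitored
#' through the per-epoch history.
#'
#' @param batchSize minibatch size (>= 2). Batches larger than the dataset
#'   degenerate to full-batch training.
#' @param learningRate Adam learning rate (> 0), shared by the VAE and the
#'   adversary optimizer.
#' @param wKL weight of the KL regularizer.
#' @param lambdaAdv weight lambda of the adversarial term; 0 disables the
#'   adversary's influence on the VAE (it is still fitted, for monitoring).
#' @param epochs number of passes over the data.
#' @param seed integer seed driving weight initialization, shuffling and the
#'   reparameterization noise; identical seeds reproduce training bitwise on
#'   a single machine.
#' @param stratify if TRUE, minibatches are composed by interleaving
#'   per-source shuffles so each batch roughly preserves source proportions;
#'   default is plain uniform shuffling.
#' @return a validated list of class `moberTrainingConfig`.
#' @export
trainingConfig <- function(batchSize = 1600L, learningRate = 1e-3,
                           wKL = 1.1e-5, lambdaAdv = 0.11,
                           epochs = 300L, seed = 0L, stratify = FALSE) {
  cfg <- list(batchSize = as.integer(batchSize),
              learningRate = learningRate, wKL = wKL,
              lambdaAdv = lambdaAdv, epochs = as.integer(epochs),
              seed = as.integer(seed), stratify = isTRUE(stratify))
  stopifnot(cfg$batchSize >= 2L, cfg$learningRate > 0,
            cfg$wKL >= 0, cfg$lambdaAdv >= 0, cfg$epochs >= 0L)
  class(cfg) <- c("moberTrainingConfig", "list")
  cfg
}

# One adversarial minibatch update. Order per the alternating scheme:
# (1) the adversary takes a gradient step on its NLL against detached
#     latent samples;
# (2) the VAE takes a step on recon + wKL*kl - lambda*advNLL, with the
#     (just-updated) adversary's weights frozen but gradients flowing
#     through it into the encoder.
# Returns updated params/optimizers plus the step's loss components
# (computed at the weights used for each forward pass).
.trainStep <- function(params, cfg, tcfg, optVae, optAdv, xb, yb) {
  n <- nrow(xb)
  K <- cfg$nSources
  S <- matrix(0, n, K)
  S[cbind(seq_len(n), yb)] <- 1

  enc <- .encodeForward(params, cfg, xb)
  eps <- matrix(rnorm(n * cfg$latentDim), n, cfg$latentDim)
  sig <- exp(enc$logvar / 2)
  z <- enc$mu + sig * eps

  advNms <- .advNames(cfg)
  advActs <- .advActs(cfg)

  # ---- adversary update (z treated as data) ----
  ffA <- .ffwd(.getLayers(params, advNms), z, advActs)
  probs <- .softmaxRows(ffA$out)
  advAcc <- mean(max.col(probs, ties.method = "first") == yb)
  dLogits <- (probs - S) / n
  bpA <- .fbwd(.getLayers(params, advNms), ffA, dLogits, advActs)
  advGrads <- .gradsToFlat(bpA$grads, advNms)
  updA <- .adamStep(params[names(advGrads)], advGrads, optAdv,
                    tcfg$learningRate)
  params[names(advGrads)] <- updA$params
  optAdv <- updA$state

  # ---- VAE update (through the frozen, updated adversary) ----
  decNms <- .decNames(cfg)
  decActs <- .decActs(cfg)
  ffD <- .ffwd(.getLayers(params, decNms), cbind(z, S), decActs)
  xhat <- ffD$out
  recon <- mean((xb - xhat)^2)
  klv <- klDivergence(enc$mu, enc$logvar)
  kl <- mean(klv)

  ffA2 <- .ffwd(.getLayers(params, advNms), z, advActs)
  probs2 <- .softmaxRows(ffA2$out)
  advNLL <- -mean(log(pmax(probs2[cbind(seq_len(n), yb)], 1e-12)))
  lossVae <- recon + tcfg$wKL * kl
  lossMober <- lossVae - tcfg$lambdaAdv * advNLL
  if (!is.finite(lossMober))
    stop("non-finite loss encountered (recon = ", signif(recon, 4),
         ", kl = ", signif(kl, 4), ", advNLL = ", signif(advNLL, 4),
         "); try a smaller learning rate")

  dXhat <- 2 * (xhat - xb) / length(xb)
  bpD <- .fbwd(.getLayers(params, decNms), ffD, dXhat, decActs)
  dz <- bpD$dX[, seq_len(cfg$latentDim), drop = FALSE]

  if (tcfg$lambdaAdv > 0) {
    dLogits2 <- -tcfg$lambdaAdv * (probs2 - S) / n
    bpA2 <- .fbwd(.getLayers(params, advNms), ffA2, dLogits2, advActs)
    dz <- dz + bpA2$dX
  }

  dmu <- dz + tcfg$wKL * enc$mu / n
  dlv <- dz * eps * 0.5 * sig + tcfg$wKL * 0.5 * (exp(enc$logvar) - 1) / n
  dlv <- dlv * (abs(enc$lvRaw) < .LOGVAR_CLAMP)

  vaeGrads <- list(
    mu.W = crossprod(enc$h, dmu), mu.b = colSums(dmu),
    lv.W = crossprod(enc$h, dlv), lv.b = colSums(dlv))
  dH <- tcrossprod(dmu, params[["mu.W"]]) + tcrossprod(dlv, params[["lv.W"]])
  encNms <- .encNames(cfg)
  bpE <- .fbwd(.getLayers(params, encNms), enc$trunk, dH,
               rep("selu", length(encNms)))
  vaeGrads <- c(vaeGrads, .gradsToFlat(bpE$grads, encNms),
                .gradsToFlat(bpD$grads, decNms))
  updV <- .adamStep(params[names(vaeGrads)], vaeGrads, optVae,
                    tcfg$learningRate)
  params[names(vaeGrads)] <- updV$params

  list(params = params, optVae = updV$state, optAdv = optAdv,
       losses = c(recon = recon, kl = kl, advNLL = advNLL,
                  lossVae = lossVae, lossMober = lossMober,
                  advAcc = advAcc))
}

#' Run a single adversarial training step
#'
#' Utility exposing one minibatch update: adversary step, then VAE step.
#' Optimizer moments are carried in `state`; pass the returned `state` back
#' in to continue. Mainly useful for step-level diagnostics; [moberFit()]
#' is the full loop.
#'
#' @param model a [MoberModel-class].
#' @param x normalized expression batch (samples x genes), >= 2 rows.
#' @param sources character vector of source labels for the batch.
#' @param config a [trainingConfig()].
#' @param state optimizer state from a previous call, or NULL to start.
#' @return list with the updated `model`, optimizer `state`, and a named
#'   numeric `losses` vector (recon, kl, advNLL, lossVae, lossMober, advAcc).
#' @export
moberTrainStep <- function(model, x, sources, config = trainingConfig(),
                           state = NULL) {
  x <- .asSampleMatrix(x, model@config$nGenes)
  if (nrow(x) < 2L)
    stop("a training batch needs at least 2 samples")
  yb <- match(as.character(sources), model@sourceNames)
  if (anyNA(yb))
    stop("unknown source label(s); registered: ",
         paste(model@sourceNames, collapse = ", "))
  params <- model@params
  if (is.null(state)) {
    vaeNms <- setdiff(names(params),
                      unlist(lapply(.advNames(model@config),
                                    function(n) paste0(n, c(".W", ".b")))))
    advNms <- setdiff(names(params), vaeNms)
    state <- list(optVae = .adamInit(params[vaeNms]),
                  optAdv = .adamInit(params[advNms]))
  }
  res <- .trainStep(params, model@config, config, state$optVae,
                    state$optAdv, x, yb)
  model@params <- res$params
  list(model = model,
       state = list(optVae = res$optVae, optAdv = res$optAdv),
       losses = res$losses)
}

.makeBatches <- function(n, batchSize, y = NULL, stratify = FALSE) {
  perm <- if (stratify && !is.null(y)) {
    # interleave per-source shuffles so batches keep source proportions
    parts <- lapply(split(seq_len(n), y),
                    function(p) p[sample.int(length(p))])
    idx <- unlist(parts, use.names = FALSE)
    pos <- unlist(lapply(parts, function(p) seq_along(p) / (length(p) + 1)),
                  use.names = FALSE)
    idx[order(pos)]
  } else {
    sample.int(n)
  }
  starts <- seq(1L, n, by = batchSize)
  batches <- lapply(starts, function(s) perm[s:min(s + batchSize - 1L, n)])
  # a trailing singleton cannot form a batch; fold it into the previous one
  sizes <- lengths(batches)
  if (length(batches) > 1L && sizes[length(batches)] < 2L) {
    batches[[length(batches) - 1L]] <-
      c(batches[[length(batches) - 1L]], batches[[length(batches)]])
    batches[[length(batches)]] <- NULL
  }
  batches
}

#' Fit a MoberModel by alternating adversarial training
#'
#' Each minibatch performs an adversary update (minimizing its source NLL on
#' detached latent samples) followed by a VAE update (minimizing
#' `recon + wKL*kl - lambdaAdv*advNLL` through the frozen adversary). At
#' equilibrium the embedding reconstructs well while the adversary is reduced
#' to chance-level source prediction.
#'
#' @param x either a numeric matrix of normalized expression (samples x
#'   genes) or a [SummarizedExperiment::SummarizedExperiment] carrying a
#'   `"logcpm"` assay (genes x samples, as produced by [logCPM()]) and a
#'   `source` column in `colData`.
#' @param sources character vector of per-sample source labels (ignored for
#'   a SummarizedExperiment, which carries its own).
#' @param config a [trainingConfig()].
#' @param modelConfig optional [moberModelConfig()]; defaults to the standard
#'   architecture sized to the data.
#' @return a trained [MoberModel-class]; `trainingHistory()` holds one row
#'   per epoch with mean loss components and the adversary's training
#'   accuracy.
#' @export
setGeneric("moberFit", function(x, sources, config = trainingConfig(),
                                modelConfig = NULL)
  standardGeneric("moberFit"))

#' @rdname moberFit
#' @export
setMethod("moberFit", "matrix", function(x, sources, config, modelConfig) {
  stopifnot(is.numeric(x))
  sources <- as.character(sources)
  if (length(sources) != nrow(x))
    stop("need one source label per sample (row)")
  srcNames <- sort(unique(sources))
  if (length(srcNames) < 2L)
    stop("training requires at least two sources; found only: ", srcNames)
  geneIds <- colnames(x)
  if (is.null(geneIds)) geneIds <- sprintf("g%04d", seq_len(ncol(x)))
  if (is.null(modelConfig))
    modelConfig <- moberModelConfig(ncol(x), length(srcNames))

  set.seed(config$seed)
  model <- moberModel(geneIds, srcNames, modelConfig)
  if (config$epochs == 0L) return(model)

  params <- model@params
  advPar <- unlist(lapply(.advNames(modelConfig),
                          function(n) paste0(n, c(".W", ".b"))))
  vaePar <- setdiff(names(params), advPar)
  optVae <- .adamInit(params[vaePar])
  optAdv <- .adamInit(params[advPar])
  y <- match(sources, srcNames)

  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- .makeBatches(nrow(x), config$batchSize, y, config$stratify)
    acc <- numeric(6); w <- 0
    for (b in batches) {
      res <- .trainStep(params, modelConfig, config, optVae, optAdv,
                        x[b, , drop = FALSE], y[b])
      params <- res$params; optVae <- res$optVae; optAdv <- res$optAdv
      acc <- acc + res$losses * length(b)
      w <- w + length(b)
    }
    m <- acc / w
    hist[[ep]] <- data.frame(epoch = ep, recon = m[1], kl = m[2],
                             advNLL = m[3], lossVae = m[4],
                             lossMober = m[5], advAcc = m[6])
  }
  model@params <- params
  model@history <- do.call(rbind, hist)
  rownames(model@history) <- NULL
  model
})

#' @rdname moberFit
#' @export
setMethod("moberFit", "SummarizedExperiment",
  function(x, sources, config, modelConfig) {
    if (!"logcpm" %in% SummarizedExperiment::assayNames(x))
      stop("SummarizedExperiment input must carry a 'logcpm' assay; ",
           "run logCPM() first")
    if (missing(sources)) {
      if (!"source" %in% colnames(SummarizedExperiment::colData(x)))
        stop("colData must have a 'source' column")
      sources <- as.character(x$source)
    }
    mat <- t(SummarizedExperiment::assay(x, "logcpm"))
    moberFit(mat, sources, config, modelConfig)
  })

#' Save / load model checkpoints
#'
#' The checkpoint is a self-describing RDS archive holding the weights,
#' architecture config, registered source names, gene universe, training
#' history and optional preprocessing settings, so projection can validate
#' its inputs. `loadCheckpoint(saveCheckpoint(m))` reproduces forward passes
#' bitwise.
#'
#' @param model a [MoberModel-class].
#' @param path file path for the checkpoint.
#' @param preprocessing optional list of preprocessing settings to embed.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the restored [MoberModel-class].
#' @export
saveCheckpoint <- function(model, path, preprocessing = list()) {
  stopifnot(is(model, "MoberModel"))
  validObject(model)
  saveRDS(list(format = "mober-checkpoint", version = 1L,
               config = model@config, params = model@params,
               sourceNames = model@sourceNames, geneIds = model@geneIds,
               history = model@history, preprocessing = preprocessing),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "mober-checkpoint"))
    stop("not a mober checkpoint: ", path)
  model <- new("MoberModel", config = obj$config, params = obj$params,
               sourceNames = obj$sourceNames, geneIds = obj$geneIds,
               history = obj$history)
  validObject(model)
  model
}
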