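# Shared fixtures. Heavier objects (trained models) are built once per test
# session and cached.

.cache <- new.env(parent = emptyenv())

# Tiny two-source dataset with two well-separated clusters; trains in
# seconds and is enough for code-path properties (projection fidelity,
# embedding geometry).
smallSimSE <- function(seed = 11L) {
  nGenes <- 40L
  set.seed(seed)
  base <- rnorm(nGenes, 2, 0.8)
  cm <- cbind(C1 = base, C2 = base)
  cm[1:10, "C1"] <- cm[1:10, "C1"] + 2
  cm[11:20, "C2"] <- cm[11:20, "C2"] + 2
  eff <- matrix(exp(rnorm(nGenes * 2, sd = 0.4)), nGenes, 2,
                dimnames = list(NULL, c("A", "B")))
  spec <- syntheticSpec(nGenes, cm, eff, matrix(40L, 2, 2),
                        libSizes = c(1, 1.4), dispersion = 0.2, seed = seed)
  logCPM(simulateCounts(spec))
}

smallTrainedModel <- function() {
  if (!is.null(.cache$smallModel)) return(.cache$smallModel)
  se <- smallSimSE()
  X <- t(SummarizedExperiment::assay(se, "logcpm"))
  fit <- moberFit(X, as.character(se$source),
                  trainingConfig(batchSize = 80L, epochs = 250L, seed = 1L),
                  moberModelConfig(ncol(X), 2L, latentDim = 8L,
                                   encoderHidden = c(32L, 16L),
                                   decoderHidden = c(16L, 32L),
                                   adversaryHidden = c(16L)))
  .cache$smallModel <- list(model = fit, se = se, X = X)
  .cache$smallModel
}

# The canonical fixture (600 x 200, 3 sources, private cluster C4) trained
# to adversarial equilibrium; one model per training seed, cached.
fixtureData <- function() {
  if (is.null(.cache$fixtureSE)) .cache$fixtureSE <- logCPM(defaultFixture())
  .cache$fixtureSE
}

fixtureTrainingConfig <- function(seed) {
  trainingConfig(batchSize = 200L, epochs = 1000L, seed = seed)
}

trainedFixtureModel <- function(seed = 0L) {
  key <- paste0("fixtureModel", seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  se <- fixtureData()
  X <- t(SummarizedExperiment::assay(se, "logcpm"))
  fit <- moberFit(X, as.character(se$source), fixtureTrainingConfig(seed))
  .cache[[key]] <- fit
  fit
}

fixtureMatrix <- function() {
  t(SummarizedExperiment::assay(fixtureData(), "logcpm"))
}
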