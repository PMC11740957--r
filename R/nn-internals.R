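# Dense-network plumbing shared by encoder, decoder and adversary.
# Parameters live in a flat named list of W (in x out) matrices and b vectors;
# forward passes cache pre-activations so the matching backward pass can run
# without recomputation. Everything is plain matrix algebra so a fixed RNG
# seed gives bitwise-reproducible training on one machine.

.SELU_LAMBDA <- 1.0507009873554805
.SELU_ALPHA <- 1.6732632423543772

.selu <- function(x) {
  .SELU_LAMBDA * ifelse(x > 0, x, .SELU_ALPHA * (exp(x) - 1))
}

.seluGrad <- function(x) {
  .SELU_LAMBDA * ifelse(x > 0, 1, .SELU_ALPHA * exp(x))
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.addBias <- function(z, b) {
  z + matrix(b, nrow(z), length(b), byrow = TRUE)
}

# LeCun-normal initialization (sd = 1/sqrt(fan_in)), the standard pairing
# with SELU activations.
.initLayer <- function(fanIn, fanOut) {
  list(W = matrix(rnorm(fanIn * fanOut, sd = 1 / sqrt(fanIn)), fanIn, fanOut),
       b = numeric(fanOut))
}

.layerNames <- function(prefix, n) {
  if (n == 0L) character() else paste0(prefix, seq_len(n))
}

.getLayers <- function(params, names) {
  lapply(names, function(nm) list(W = params[[paste0(nm, ".W")]],
                                  b = params[[paste0(nm, ".b")]]))
}

# Forward through a layer stack; acts is one of "selu", "relu", "linear"
# per layer. Returns output plus caches (inputs As and pre-activations Zs).
.ffwd <- function(layers, x, acts) {
  L <- length(layers)
  As <- vector("list", L + 1L)
  Zs <- vector("list", L)
  As[[1L]] <- x
  for (l in seq_len(L)) {
    z <- .addBias(As[[l]] %*% layers[[l]]$W, layers[[l]]$b)
    Zs[[l]] <- z
    As[[l + 1L]] <- switch(acts[l],
      selu = .selu(z),
      relu = pmax(z, 0),
      linear = z,
      stop("unknown activation: ", acts[l]))
  }
  list(out = As[[L + 1L]], As = As, Zs = Zs)
}

# Backward pass matching .ffwd; dOut is dLoss/d(output). Returns per-layer
# gradients and dLoss/d(input).
.fbwd <- function(layers, cache, dOut, acts) {
  L <- length(layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- switch(acts[l],
      selu = dA * .seluGrad(cache$Zs[[l]]),
      relu = dA * (cache$Zs[[l]] > 0),
      linear = dA)
    grads[[l]] <- list(W = crossprod(cache$As[[l]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

.gradsToFlat <- function(grads, names) {
  out <- list()
  for (i in seq_along(names)) {
    out[[paste0(names[i], ".W")]] <- grads[[i]]$W
    out[[paste0(names[i], ".b")]] <- grads[[i]]$b
  }
  out
}

# Adam optimizer over a flat parameter list; state holds first/second
# moments per tensor and the shared step counter.
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
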