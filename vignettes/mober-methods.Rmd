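---
title: "Multi-origin expression integration with an adversarial conditional VAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-origin expression integration with an adversarial conditional VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mober)
library(SummarizedExperiment)
```

## The problem

Bulk transcriptomes of cancer cell lines, patient-derived xenografts (PTX)
and clinical tumor cohorts cannot be compared directly: profiles separate by
*origin* (growth conditions, stromal and immune contamination, cohort-level
technical artifacts) before they separate by biology. `mober` learns a latent
representation of expression profiles that keeps biological structure while
carrying no information about which dataset a sample came from, and can
*decode any sample as if it originated from another source* — e.g. render a
cell line's transcriptome in the style of a clinical tumor cohort.

## Model

Each sample is a vector $x$ of $\log_2(\mathrm{CPM}+1)$ values on a common
gene set. A conditional variational autoencoder (VAE) encodes $x$ into a
diagonal-Gaussian posterior $Q(z \mid x) = N(\mu, \mathrm{diag}\,e^{\ell})$
over a 64-dimensional latent space, samples $z = \mu + e^{\ell/2}\epsilon$
(the reparameterization trick), and decodes $z$ *conditionally*: the decoder
also receives a one-hot vector $s$ over the $K$ registered sources,
concatenated to $z$ at its first layer. Because origin information is handed
to the decoder explicitly, the encoder has no incentive to keep it in $z$ —
and an adversary makes retaining it actively costly.

The adversarial network is a softmax classifier that tries to recover the
source label from the sampled $z$. Training alternates two updates per
minibatch:

1. the **adversary** minimizes its negative log-likelihood
   $\mathcal{L}_{\mathrm{aNN}} = -\mathbb{E}[\log p(s \mid z)]$ on the
   current embeddings (gradients do not reach the encoder);
2. the **VAE** minimizes the joint objective
   $\mathcal{L} = \mathcal{L}_{\mathrm{VAE}} -
   \lambda\,\mathcal{L}_{\mathrm{aNN}}$, with
   $\mathcal{L}_{\mathrm{VAE}} = \mathrm{recon} + w_{KL}\,\mathrm{KL}[Q(z\mid
   x) \,\|\, N(0, I)]$, gradients flowing through the frozen adversary into
   the encoder.

At equilibrium the embedding reconstructs well while the adversary is
reduced to chance. A gradient-reversal single-optimizer scheme is the other
standard realization of the same minimax objective; alternating updates were
chosen as the more stable of the two and are the only mode implemented.

### Reconstruction likelihood

The decoder's output distribution is modelled as an isotropic Gaussian on
log-CPM values, so the reconstruction term is a mean squared error. We
report and optimize it **averaged over genes and samples** (a per-value
MSE), not summed over genes. With a summed reconstruction error the term
scales with the size of the gene universe (hundreds to tens of thousands),
and the default weights $w_{KL} = 1.1\times10^{-5}$ and $\lambda = 0.11$
would be dwarfed — the adversarial gradient would be orders of magnitude too
weak to strip source information at any gene count. Per-value averaging
keeps the three loss components on commensurate scales for any input
dimension, which is the only reading under which the reference defaults are
self-consistent. The KL term keeps its conventional per-sample form
$\tfrac12\sum_d(\mu_d^2 + e^{\ell_d} - 1 - \ell_d)$, averaged over the
batch.

### Architecture

* encoder: genes → 256 → 128 → 64, SELU activations; linear heads give
  $\mu$ and $\ell$ (latent dimension 64 — the last encoder width feeds the
  heads);
* decoder: $[z, s]$ → 64 → 128 → 256 → genes, SELU hidden, final **ReLU**
  so decoded $\log_2(\mathrm{CPM}+1)$ values are non-negative. The decoder
  mirrors the encoder (expansion toward the output), the standard
  autoencoder shape;
* adversary: $z$ → 64 → 32 → $K$, SELU hidden, softmax output. Its hidden
  widths are a free choice; 64/32 keeps it expressive but cheap.

No batch normalization or dropout is used anywhere. Weights are initialized
LeCun-normal, the standard pairing with SELU.

### Numerical choices

* `logvar` is clamped to $[-20, 20]$; the clamp mask zeroes gradients where
  active.
* softmax probabilities are clamped at $10^{-12}$ before logs, so a
  confidently wrong adversary produces a large finite loss.
* Optimization uses Adam (learning rate $10^{-3}$, $\beta = (0.9, 0.999)$,
  $\epsilon = 10^{-8}$) with separate optimizer states for the VAE and the
  adversary.
* All randomness (initialization, shuffling, reparameterization noise)
  flows from the single integer seed in `trainingConfig()`; two runs with
  the same seed agree bitwise on one machine.
* A trailing minibatch of a single sample is folded into the previous
  batch (batch statistics are undefined at $n=1$).

## Preprocessing

Datasets are subset to the genes present in all inputs
(`intersectGenes()`, lexicographically sorted so independent runs agree
exactly; the caller supplies gene universes, e.g. pre-filtered to
protein-coding genes). Indications with fewer than 5 samples are dropped
(`filterSmallIndications()`; unannotated samples are retained). Library
sizes are normalized by trimmed mean of M-values via edgeR (30% trim on
log-ratios, 5% on abundances, precision-weighted mean, reference = sample
with upper quartile closest to the mean upper quartile; factors have
geometric mean 1), then transformed to $\log_2(\mathrm{CPM} + 1)$ —
pseudocount added to the CPM before the log, so a zero count maps to
exactly 0 and values are non-negative. When several datasets are given they
are normalized jointly after gene intersection; per-dataset normalization
is available by calling `tmmFactors()` per dataset. Genes with zero counts
everywhere are retained.

## Projection

`moberProject(model, x, targetSource)` encodes each sample and decodes with
the one-hot source swapped. The default uses the posterior mean $\mu$
(`mode = "mean"`), making projections deterministic and reproducible for
downstream analysis; `mode = "sampled"` draws $z$ under a seed. Projection
never changes sample count, gene count or ordering, and projecting data to
its own source is plain reconstruction.

## Evaluation

The alignment diagnostics mirror how cross-dataset agreement is assessed in
practice:

* `pcaEmbed()` fits principal components on a reference set (centered, not
  scaled — scaling would inflate low-variance genes; 70 components by
  default) and transforms queries with the reference's center and loadings,
  avoiding query leakage into the fit.
* `nnClassify()` assigns each query the majority label among its 25 nearest
  reference neighbors (Euclidean). Vote ties break by smaller summed
  distance, then lexicographic label order — fixed rules so results are
  deterministic.
* `differentialExpression()` is a per-gene Welch $t$-test on log-space
  values with Benjamini–Hochberg correction; the reported table is the
  genes with adjusted $p$ below 0.01 ranked by absolute fold change,
  truncated to 100. Welch is the safer default when group variances differ
  (`varEqual = TRUE` selects Student's variant). Genes with zero variance
  in both groups get $p = 1$ and a flag.
* `batchMixingEntropy()` quantifies "sources are intermixed": per-sample
  Shannon entropy of the source composition among $k$ nearest neighbors,
  normalized by $\ln K$.
* `knnProbeAccuracy()` is the leakage probe: a fresh 5-NN classifier
  trained on a deterministic half-split of an embedding; its held-out
  accuracy measures how much label information the embedding retains.

## The synthetic fixture

Real multi-cohort compendia cannot ship with a package, so the generator
(`syntheticSpec()` / `simulateCounts()`) emulates the structure the method
must disentangle: negative-binomial counts whose mean is
$\mathrm{libSize}_s \cdot e^{m_{gc}} \cdot f_{gs}$ for cluster profile $m$,
multiplicative per-gene source effect $f$, and per-source library scale.
Multiplicative gene-wise effects reproduce the mean–variance structure of
RNA-seq and give both TMM and the adversary real work. The canonical
fixture (`defaultFixture()`): 200 genes, 600 samples, 3 sources × 4
clusters with cluster C4 private to source S1, dispersion 0.3, source
effects log-normal$(0, 0.5^2)$, library scales $(1, 1.5, 0.7)$, 25 marker
genes per cluster shifted by $+2$ in log-mean, seed 0. Under these
conditions a 5-NN source classifier on log-CPM exceeds 0.8 accuracy — the
batch effect dominates — while clusters remain separable in PCA space.

What the fixture does **not** emulate: gene–gene correlation beyond cluster
structure, compositional stromal/immune gradients (the real driver of
model-vs-tumor differences), outlier samples, varying per-sample library
sizes within a source, and realistic gene counts. Passing on the fixture
shows the machinery removes strong mean-shift batch effects while keeping
cluster geometry; it does not certify performance on real cohorts.

### Training budget at fixture scale

The reference recipe (minibatch 1600, Adam at $10^{-3}$) is tuned for
cohorts of $10^4$ samples and $1.7\times10^4$ genes. On the 600-sample
fixture a batch of 1600 degenerates to full-batch training and 300 epochs
means only 300 optimizer steps — far too few for the minimax game to reach
equilibrium. Fixture runs therefore use minibatches of 200 and 1000 epochs
(≈5000 steps, about 2–3 minutes on one CPU core): monitored trajectories
show the source probe collapsing to chance between 700 and 1000 epochs
while the cluster ARI stays above 0.98. These are the problem sizes used
throughout the test suite and the acceptance script.

## Known limitations

* The decoder likelihood is Gaussian on normalized values; counts are not
  modelled directly (no negative-binomial or zero-inflated decoder).
* $\lambda$ and $w_{KL}$ follow the reference defaults
  ($11\times10^{-2}$, $11\times10^{-6}$); both are exposed because the
  balance of the minimax game depends on data scale.
* Single-device, single-precision-agnostic training only; no early
  stopping, no hyperparameter search.
* Delimited-text I/O only; no HDF5 container support.
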