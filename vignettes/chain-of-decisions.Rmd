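---
title: "A three-stage chain of decisions for personalized medication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-stage chain of decisions for personalized medication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codchain)
```

## The decision chain

Choosing a medication regimen for a chronic-disease patient is naturally a
sequence of three dependent decisions: how severe is the disease, which
medication combinations are effective at all, and which of those
combinations fit *this* patient. `codchain` models the three decisions as
three trained models arranged in an upstream–downstream chain: the severity
model produces per-patient embeddings, the combination-efficacy model
produces per-regimen embeddings, and the matching model aligns the two sets
in a shared space and ranks regimens per patient by cosine confidence.

Because clinical data of this kind are private, the package treats a
synthetic-cohort generator as a first-class component: every stage of the
chain can be validated by checking that it recovers signal that the
generator planted.

## Stage 1: severity from fused modalities

Laboratory indicators are encoded FT-Transformer style. Numeric field $j$
with value $x_j$ becomes the token $x_j w_j + b_j$ with learned per-field
vectors; each categorical field contributes a per-category learned
embedding (plus a reserved out-of-vocabulary row); a learned CLS token is
appended, and the $(n+m+1) \times d$ token matrix passes through $L$
self-attention + feed-forward layers. Fields are an unordered set, so no
positional encodings are used and the encoder is permutation-invariant
over field tokens (a property the test suite checks exactly). The CLS
output is the table embedding $E_\mathrm{Table}$.

Image evidence enters as precomputed per-image feature vectors behind a
pluggable interface; a patient's vectors are averaged and linearly
projected to the shared width $d$, giving $E_\mathrm{Image}$. Fusion is
cross-attention with queries from the table path,

$$E_\mathrm{Fusion} = \mathrm{LN}\!\left(E_\mathrm{Table} +
  \mathrm{softmax}\!\big(E_\mathrm{Table} W_Q (E_\mathrm{Image} W_K)^\top /
  \sqrt{d}\big)\, E_\mathrm{Image} W_V\right),$$

with a residual from the query path and layer normalization. Because the
per-patient image tokens are averaged before fusion there is a single key,
the softmax collapses to 1, and the attended value reduces to
$E_\mathrm{Image} W_V$; the general multi-token form is implemented and
tested against a dense oracle.

Two auxiliary linear heads on the unimodal embeddings produce
classification losses $L_\mathrm{Image}$ and $L_\mathrm{Table}$
(cross-entropy; the losses are "classification losses" and cross-entropy
is the standard choice). The L2 norms of their gradients, each taken over
its own modality's encoder-plus-head parameters, quantify how much each
modality is currently driving learning:

$$\|\nabla L_m\|_2, \quad m \in \{\mathrm{Image}, \mathrm{Table}\}, \qquad
  L_\mathrm{GradNorm} = \|\nabla L_\mathrm{Image}\|_2 +
  \|\nabla L_\mathrm{Table}\|_2 .$$

The two norms are fed — as plain numbers, detached from differentiation —
into a three-layer projection network (linear, ReLU, linear, sigmoid,
linear, softmax) yielding modality weights $w_\mathrm{Image} +
w_\mathrm{Table} = 1$, and those weights pass through a two-layer softplus
network giving the strictly positive fusion weight $w_\mathrm{Fusion}$.
The training objective is

$$L = w_\mathrm{Image} L_\mathrm{Image} + w_\mathrm{Table} L_\mathrm{Table}
    + w_\mathrm{Fusion} L_\mathrm{Multimodal} + L_\mathrm{GradNorm}.$$

Three numerical choices here were genuinely open and deserve a record:

* **Neutral weight-net initialization.** The output layer of the modality
  weight network starts at zero, so the weights begin at exactly
  $(0.5, 0.5)$ and move only under the training signal rather than under
  the accident of random initialization.
* **Detached fusion-weight input.** The modality-weight vector enters the
  fusion-weight network as a detached value. If it stays on the
  differentiation path, the gradient of $w_\mathrm{Fusion} \cdot
  L_\mathrm{Multimodal}$ flows backwards *through* the fusion-weight
  network into the modality softmax with arbitrary sign and a magnitude
  that can dwarf the direct loss-comparison signal, locking the weights
  onto whichever modality the random geometry favours. Treating
  downstream weight consumers as observers of the weights (exactly as the
  gradient norms themselves are treated) removes the interference; with
  this choice the weights reliably migrate to the informative modality.
* **Detached gradient norms.** The norms act as inputs to the weight
  network, not as differentiable paths, so no second-order terms are
  computed. $L_\mathrm{GradNorm}$ enters the total loss as the (constant
  per batch) sum of the two norms.

Training is mini-batch Adam (defaults: $d = 64$, 2 layers, 4 heads,
learning rate $10^{-3}$, 50 epochs, batch 32, decoupled weight decay
$10^{-3}$), with z-scoring of numeric fields by development-set statistics.
All tunables sit in `stage1_config()`. The per-epoch weight trajectory is
recorded in the fitted object and plotted by `plot()`.

## Stage 2: combination efficacy over regimen graphs

A regimen is a graph whose nodes are its medications. Node features
concatenate three attribute views,
$h_i = [\,F_\mathrm{macro} \,|\, F_\mathrm{micro} \,|\, F_\mathrm{ppi}\,]$:

* $F_\mathrm{macro}$ — pharmacology text attributes (meridian tropism,
  nature/property, flavours, side effects) embedded by a pluggable text
  embedder and fused by self-attention over the attribute tokens with mean
  pooling;
* $F_\mathrm{micro}$ — target-protein sequences embedded by a pluggable
  sequence embedder and averaged over the medication's targets;
* $F_\mathrm{ppi}$ — DeepWalk embeddings of the PPI network (uniform
  random walks, skip-gram with negative sampling, written in-package),
  averaged over the targets.

The shipped embedders are deterministic, dependency-free synthetic
stand-ins honouring the contracts a pre-trained language model would
satisfy: a feature-hashing character-trigram embedder for text and a
k-mer-count embedder with a fixed random projection for sequences. They
carry real signal (medication identity; block-biased sequence
composition) but none of the semantics a pre-trained encoder would add.

Regimen graphs are complete over their medications. Edge $ij$ carries the
prescription co-occurrence prior $w_{ij} =
\mathrm{cooc}(i,j)/\max \mathrm{cooc}$, so weights lie in $(0,1]$; pairs
never seen together get the fallback $1/\max \mathrm{cooc}$ — the weight a
pair observed once would have, i.e. the smallest supported prior belief.
Two edge-aware graph-transformer layers update the nodes:

$$\alpha_{ij} = \mathrm{softmax}_{j \in N(i)}\!\left(\frac{h_i W_Q (h_j W_K
  + w_{ij})^\top}{\sqrt{d_k}}\right), \qquad
  h_i' = \sigma\!\Big(\sum_{j \in N(i)} \alpha_{ij}\, h_j W_V\Big),$$

with the scalar $w_{ij}$ broadcast-added to every component of the key
vector (the minimal reading of a scalar-plus-vector sum), ReLU as
$\sigma$, and a self-loop fallback for isolated nodes. A VAE then aligns
the node features in a Gaussian latent space: the encoder emits
$(\mu_i, \sigma_i)$ with $\sigma_i = e^{\mathrm{logvar}/2} > 0$,
$z_i = \mu_i + \sigma_i \odot \varepsilon$, and

$$L_\mathrm{KL} = \tfrac{1}{2} \sum (\mu_i^2 + \sigma_i^2 -
  \log \sigma_i^2 - 1),$$

summed over latent dimensions and averaged over nodes. Mean pooling over
$z$ gives the regimen embedding $E_\mathrm{medication}$; a linear head on
it is trained under $L_\mathrm{total} = L_\mathrm{KL} + L_\mathrm{focal}$
with the focal loss $-\alpha_t (1-p_t)^\gamma \log p_t$ ($\gamma = 2$).

Two numerical choices matter here:

* **Per-dimension KL weighting.** In the training objective the KL term
  is weighted $1/\mathrm{latent}$ by default, so the alignment pressure is
  per latent dimension and does not grow with latent width. With the raw
  sum over 16 dimensions weighted 1 against a focal term, the posterior
  collapses to the prior at these problem scales and the latent carries no
  class signal. The encoder log-variance also starts at $-2$
  ($\sigma \approx 0.37$) so reparameterization noise does not drown the
  signal before the encoder settles. `kl_weight = 1` restores the literal
  objective.
* **Class-balanced $\alpha_t$.** $\alpha_t$ is the class-balance factor
  of the focal loss; by default it is set from the inverse frequency of
  each class in the training labels, the convention recommended for
  imbalanced data (which is the loss's stated purpose here). A uniform
  scalar merely rescales the objective; under 1:9 imbalance it leaves the
  minority class unlearnable.

`rank_pairwise_combinations()` scores every unordered medication pair as a
two-node regimen and keeps the top fraction (default 15%,
ceiling-counted), descending, with lexicographic tie-breaks.

## Stage 3: contrastive matching

Patient and regimen embeddings are projected by two-layer MLPs into a
shared space. Training minimizes the bidirectional margin loss: per
anchor, the hinged triplet term
$\max(0,\, s(a, r^-) - s(a, r^+) + \alpha)$ with cosine similarity $s$ and
margin $\alpha = 0.2$, averaged over anchors, halved, computed in both
directions and averaged. The as-printed unhinged form (whose literal
minimization would drive positive similarity down) is available behind
`hinge = FALSE`; the hinged reading is the one consistent with a margin
"enforcing separation strength". Negatives are in-batch: each anchor's
negative is another batch member's positive, re-sampled each batch.
Matching confidence is the cosine of the projected embeddings;
`rank_regimens()` sorts a library by confidence (ties by regimen id) and
`hit_at_k()` evaluates retrieval. Defaults: recommend $k = 5$, evaluate
HIT\@10.

## The synthetic cohort and what it can show

`synth_config()` fixes the reference study conditions:

* 600 patients, two severity classes, 8 numeric + 3 categorical
  laboratory fields, 16-dimensional image embeddings (1–2 images per
  patient). Each patient has latent tabular and image factors; the label
  is Bernoulli in $\mathrm{logit} = \beta_\mathrm{table} t +
  \beta_\mathrm{image} v$, and the observed features are noisy linear
  images of their factor. $\beta_\mathrm{image} = 0$ therefore makes
  images exactly uninformative. The default $\beta_\mathrm{table} = 4$
  puts the information ceiling of the *observed* tabular features (a
  logistic-oracle cross-validated AUROC) near 0.90, leaving clear headroom
  between a correct model and the chance-level image modality; a weaker
  signal whose ceiling sits at the recovery margin itself cannot
  discriminate a correct implementation from a broken one.
* 30 medications, 400 regimens of size 2–4 drawn with uneven popularity;
  the outcome score is the sum of per-medication effects (sd 1.5) plus 15
  planted pairwise synergies (sd 1.5) plus noise (sd 0.3), thresholded at
  a configurable quantile (0.5 balanced, 0.9 for 1:9 imbalance). The
  synergy structure makes efficacy irreducibly pairwise while keeping an
  additive backbone a pooled readout can learn.
* a 2-block stochastic-block-model PPI over 60 proteins
  ($p_\mathrm{within} = 0.25$, $p_\mathrm{between} = 0.02$), medications
  targeting 1–3 proteins biased to a home block, and synthetic amino-acid
  sequences with block-specific composition bias so the k-mer embedder
  carries block signal consistent with the network.
* matched patient–regimen pairs sharing a 4-dimensional latent factor
  observed through fixed linear maps with noise sd 0.1.

What passing tests on these cohorts show — and do not show. They show the
machinery is correct: losses match their closed forms, attention matches
dense oracles, training recovers planted modality weights, pairwise
synergies, network blocks, and pairings well above shuffled-label and
chance nulls, deterministically under a seed. They do not show clinical
performance: the generator's marginals are Gaussian and its effects
linear-plus-pairwise, far simpler than real laboratory panels, pathology
encoders or prescription practice, and the synthetic embedders carry no
pharmacological semantics. Numbers obtained here do not transfer to any
clinical dataset.

In the full chain the stage-3 inputs are the *trained* stage-1 and
stage-2 embeddings, whose geometry is only weakly coupled across stages in
the generator; full-chain HIT\@k is therefore well above chance but far
below the planted-pairing benchmark, and the chain run is read as a
smoke/reproducibility check rather than a retrieval benchmark.

## Problem sizes, tolerances, degenerate inputs

The validation suite runs at reduced scales chosen to keep the planted
signals comfortably recoverable: stage-1 encoders at $d = 16$ with one
layer and 15 epochs; stage-2 at $d_k = 48$, 60 epochs; stage-3 at 40
epochs over 200 pairs; DeepWalk block recovery on 30-protein networks
over 20 seeds. Oracle comparisons are at $10^{-6}$, closed forms at
$10^{-12}$, finite-difference checks at $10^{-4}$ relative or better.

Degenerate inputs are handled explicitly: zero vectors in cosine
similarity return 0 with a warning; empty texts and target-less
medications embed to flagged zero vectors; isolated network nodes get
zero DeepWalk vectors and a self-loop fallback in graph attention; a
focal-loss $p_t = 0$ is clipped at $10^{-12}$ with a warning; missing
images at inference either error or zero-impute by configuration;
out-of-range laboratory values are blanked *before* medians are computed
so outliers never contaminate the imputation; oversampling duplicates
whole records (no jitter) and never touches the test split. Categorical
missing values take the modal category — the paper-gap rule consistent
with median imputation for numerics. Out-of-range values blank only the
value, not the patient.

## Known limitations

The autodiff engine is minimal by design (dense matrices, no broadcasting
beyond what the models need, no kernels); it is fast enough for
desk-scale cohorts, not for real imaging corpora. Stage-2 supervision
here is the per-regimen efficacy label; patient-severity supervision is
representable by relabelling regimen graphs but is not separately
benchmarked. The chain treats exactly two modalities; the fusion
equations are strictly bimodal and no attempt is made to generalize.
Pre-trained encoder weights are out of scope by construction — the
embedder contracts are where they would plug in.
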