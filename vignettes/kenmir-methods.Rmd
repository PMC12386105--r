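---
title: "Knowledge-enhanced miRNA networks and module biomarkers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-enhanced miRNA networks and module biomarkers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kenmir)
```

## The problem

Single differentially expressed miRNAs are often weak and unstable disease
markers; miRNAs act cooperatively, and *modules* of jointly discriminative
miRNAs tend to replicate better. `kenmir` identifies such module biomarkers
from a two-group expression matrix (cases vs controls) while borrowing
strength from curated miRNA–disease association knowledge (dbDEMC- or
miRCancer-style binary tables). The pipeline has four stages, each exposed
as ordinary functions.

## 1. Cooperation network

For every pair of miRNAs $(f_i, f_j)$ a soft-margin linear SVM fitted on the
two expression columns yields a hyperplane
$\alpha_{ij} f_i + \beta_{ij} f_j + \gamma_{ij} = 0$. The left-hand side,
evaluated per sample, is the pair's *artificial combinatorial feature*
$f_{com}$; a two-sided two-sample t-test on $f_{com}$ between the groups
measures whether the pair's joint axis separates cases from controls. The
cooperation network $A_{co}$ places an edge wherever $p < 0.05$
(`p_edge`). Node attributes concatenate the binary disease-association
profile $d(f_i)$ (length $p$) with the expression profile $s(f_i)$ (length
$n$).

Design choices the underlying description leaves open, and what this
package does:

* **Standardization.** Features are z-scored on the training samples before
  every SVM fit (`standardize = TRUE`); linear SVMs are scale-sensitive.
* **t-test variant.** Welch by default (`t_test_variant`), pooled-variance
  Student optional.
* **No multiple-testing correction** across the $m(m-1)/2$ tests: the edge
  rule is the raw threshold, exposed as `p_edge`.
* **Degenerate pairs.** A pair containing a zero-variance feature is
  skipped (no edge); a combinatorial feature constant within both groups
  gives $p = 1$ when the group means agree and $p = 0$ when they differ.

A caveat worth knowing: because the hyperplane is fitted on the same samples
the t-test uses, the test is optimistically biased. Under a global null the
empirical edge rate sits above the nominal `p_edge` and varies with sample
size. This is intrinsic to the construction (the combination is *selected*
to separate the groups); interpret $A_{co}$ as a candidate-generation step,
not as a calibrated multiple-testing procedure.

## 2. Graph auto-encoder enhancement

A two-layer graph-convolutional encoder with ELU activation maps the
attribute matrix to latent representations,
$Z = \hat A\,\mathrm{ELU}(\hat A X W_0) W_1$, with
$\hat A = \tilde D^{-1/2}(A_{co}+I)\tilde D^{-1/2}$, and an inner-product
decoder reconstructs the adjacency, $A_{rec} = \sigma(Z Z^\top)$. Training
minimizes

$$L_{total} = L_{rec} + \lambda_1 L_{fc} + \lambda_2 L_{mp}$$

* $L_{rec}$: mean squared error between $A_{co}$ and $A_{rec}$, evaluated
  each epoch on all edges plus an equal number of uniformly resampled
  non-edges (`neg_sample_ratio`, per-epoch sampling without replacement;
  full-matrix MSE when sampling is disabled or the graph has no edges).
* $L_{fc}$ (functional consistency): the squared Frobenius distance between
  the Gaussian interaction profile (GIP) kernel similarity of the
  disease profiles, $GS_{ij} = \exp(-r\,\lVert d(f_i)-d(f_j)\rVert^2)$ with
  $r = 1/\overline{\lVert d(f_k)\rVert^2}$, and the same kernel computed on
  the rows of $Z$ (each with its own bandwidth). This encodes the premise
  that miRNAs with similar disease associations are functionally similar.
* $L_{mp}$ (difference prompt): per-feature pseudo-labels mark differential
  expression (raw per-feature t-test, $p<0.05$); a linear discriminator
  $D_L$ followed by L2 normalization and a temperature-$\tau$
  supervised-contrastive loss pulls together representations sharing a
  pseudo-label and pushes the rest apart. Features whose pseudo-label class
  is a singleton contribute no term.

Defaults follow the method's reference settings: $\lambda_1 = 0.1$,
$\lambda_2 = 10^{-7}$, learning rate $0.01$, 200 epochs, $\tau = 0.1$.
Choices that were genuinely open:

* **Optimizer.** Adam at the stated learning rate; gradients are analytic
  and verified against central finite differences in the test suite
  (relative error below $10^{-4}$ per parameter block).
* **Architecture widths.** $h_1 = 64$, $h_2 = 32$, discriminator output 16
  (`hidden_dims`, `discr_dim`).
* **Initialization.** Seeded fan-scaled (Glorot-style) uniform; one seeded
  generator drives initialization and negative sampling, so a seed fixes
  the run bit for bit.
* **Attribute scaling.** Attribute columns are z-scored across nodes before
  encoding. Raw expression scales otherwise push the initial latent dot
  products deep into the decoder's saturated range, where $L_{rec}$ has
  vanishing gradients and training stalls; column standardization keeps the
  initial decoder outputs near 0.5.
* **Discriminator normalization.** $L_{mp}$'s inner product is taken on
  L2-normalized discriminator outputs (`normalize_discriminator`), which
  bounds the logits at $1/\tau$; the unnormalized variant is available.

### From $Z$ to the enhanced network

The decoder probability $w_{ij} = \sigma(z_i \cdot z_j)$ scores every pair.
`build_enhanced_network()` keeps pairs with $w_{ij} \ge \theta$
(`edge_threshold`, default 0.5 — the decoder's decision boundary). The
pipeline additionally restricts candidates to the edges of $A_{co}$: the
enhancement is read as *denoising* — false-positive cooperation edges are
the stated problem, so the enhanced network drops $A_{co}$ edges whose
reconstruction probability falls below $\theta$ and reweights the rest,
rather than proposing pairs the data never supported. Unrestricted
thresholding is available through the function's default interface, but on
partially trained representations roughly half of all pairs have a
nonnegative latent dot product, which yields near-complete graphs and
defeats the purpose; the restricted rule is the package's documented
choice.

## 3. Greedy module search

Node importance is the weighted degree. Each module starts at the most
important remaining node; at every step the maximum-weight edge from the
module to the outside proposes a candidate (edge-weight ties go to the
candidate whose addition yields the best AUC, residual ties to the
lexicographically smallest id). The candidate joins if it strictly improves
the module's AUC; otherwise it joins with probability
$\mathrm{Prob}_t = 1 - \exp((\mathrm{AUC}_{cmn} - 1)/cmn)$, where $cmn$
counts the module plus the candidate. A rejection ends the module; found
modules are removed and the search repeats until no edges remain or
`max_modules` is reached. The `k` highest-AUC modules feed one linear SVM
each; prediction is by majority vote (ties resolved by the mean decision
score).

* **Module AUC.** The description does not fix how AUC is computed during
  search. Resubstitution AUC of a trained SVM saturates at 1 almost
  immediately, so the default is seeded stratified 5-fold cross-validation
  on the training samples with held-out decision scores pooled before the
  rank-formula AUC (ties counted 0.5). `auc_mode = "resub"` restores
  resubstitution. Fold assignment derives deterministically from the seed
  and the member set, so results do not depend on evaluation order.
* **Stop rule.** A single probabilistic rejection terminates the module's
  growth; rejected candidates are not revisited.
* **Improvement is strict** (`>`): an exactly equal AUC goes through the
  probabilistic gate, and $\mathrm{Prob}_t = 0$ at AUC $= 1$, so perfect
  modules stop growing.

## 4. Evaluation harness

`cross_validate()` runs repeated stratified k-fold cross-validation
(default 10 × 10) refitting the *entire* pipeline — network, auto-encoder,
module search, ensemble — on every training split; accuracy, sensitivity
and specificity come from held-out folds only and are reported in percent
as mean ± SD over all fold evaluations. Refitting per fold avoids
test-set leakage into the network topology; a `coop` argument to
`run_pipeline()` lets callers reuse a cooperation network across ablation
variants of the *same* training split, where that reuse is sound because
the topology does not depend on the ablation flags.

## The synthetic benchmark

`simulate_dataset()` draws two-group data with planted modules:
equicorrelated Gaussian blocks (pairwise correlation $\rho$, unit variance)
shifted by $+\delta$ in cases, independent background noise, and a
knowledge table in which each planted module owns a distinct disease block
(members share its rows; background rows are sparse), with every entry
flipped independently at rate $\varepsilon$. The reference conditions used
throughout the tests are 30 samples per group, $m = 120$ features, three
modules of 8 with $\rho = 0.6$ and $\delta = 1.5$, $p = 20$ diseases,
$\varepsilon = 0.05$ — sample and feature counts in the range of public
two-group miRNA microarray datasets, an effect size that makes single
features informative but imperfect, and mild knowledge noise. Null
calibration uses $\delta = 0$, $\rho = 0$.

What the generator does *not* emulate: heavy-tailed and heteroscedastic
microarray noise, batch effects, probe-level artifacts, correlated
background features, and incomplete or biased knowledge coverage beyond
uniform flips. Passing the benchmark therefore demonstrates algorithmic
correctness and the intended qualitative behavior, not performance on real
cohorts.

## Known limitations

Two structural effects surfaced by the benchmark deserve emphasis.

* **Hub collapse.** When an effect is strong enough that a feature forms a
  significant pair with *every* other feature, its row of $A_{co}+I$ is the
  all-ones row. A graph-convolutional encoder assigns identical latent
  vectors to nodes with identical adjacency rows, and gradient updates
  preserve the identity — no attribute information, including knowledge,
  can separate such nodes. Under the reference conditions all planted
  features are full-degree hubs, so the planted partition into three
  modules is unrecoverable by construction, and measured module–truth
  Jaccard overlap plateaus around 0.2 even as held-out classification
  accuracy exceeds 90% and the enhanced network removes cross-module edges
  in every seed. On real data, where effects are weaker and degrees vary,
  the collapse is partial rather than exact.
* **AUC-guided mixing.** Adding an independent informative feature raises a
  module's AUC more than adding a correlated same-module feature, so the
  greedy search prefers mixed modules whenever the graph permits. Module
  *interpretation* should rest on the network structure and knowledge, not
  on membership alone.

Both effects are properties of the method under strong-signal conditions,
reported here so that users calibrate expectations; neither affects the
classification quality of the resulting ensemble.

## Reproducibility and problem sizes

Every stochastic step (initialization, negative sampling, fold assignment,
the probabilistic acceptance gate) derives from `run_config()$seed`;
identical seed and configuration reproduce module files and manifests byte
for byte. The test suite and the acceptance script run the reference
benchmark at $m = 120$, $n = 60$ over ten seeds with the full pipeline and
all three ablation variants, and the null checks at $m = 2000$ features
(pseudo-label calibration) and a 5-fold × 2-repeat cross-validation on
24 null features — sizes chosen so a complete run stays comfortable on a
single CPU while every stage is exercised end to end.
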