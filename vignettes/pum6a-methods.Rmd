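---
title: "Detecting m6A from nanopore reads with attention-based PU multi-instance learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting m6A from nanopore reads with attention-based PU multi-instance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pum6a)
```

## The problem

N6-methyladenosine (m6A) is the most common internal mRNA modification.
Nanopore direct RNA sequencing preserves modifications on native molecules:
a methylated adenosine perturbs the ionic current as the base transits the
pore and inflates base-calling errors around it. Site-level callers face two
structural difficulties:

* **Read-level labels do not exist.** Antibody- or chemistry-based ground
  truth (miCLIP, m6ACE-seq, GLORI) marks *sites*, never individual reads,
  and a site is modified on only a fraction of its transcripts (its
  *stoichiometry*).
* **Site-level labels are incomplete.** Every experimental protocol
  underestimates the true site set, so "not in the truth set" cannot be
  read as "unmodified" — training data are positive-and-unlabeled (PU),
  not positive-and-negative.

`pum6a` treats each candidate site (an RRACH motif occurrence on a
transcript) as a *bag* of reads and each read's 40-dimensional feature
vector as an *instance*. Under the multi-instance assumption the bag label
is the OR of the (hidden) instance labels: a site is called modified iff at
least one read carries the modification.

## Model

Each read's feature vector $x_k \in \mathbb{R}^{40}$ is embedded by a
two-layer feed-forward network with ReLU activations,
$h_k = f_\varphi(x_k) \in \mathbb{R}^M$. A bag
$\{h_1,\dots,h_k\}$ is pooled by gated-tanh attention

$$a_j = \frac{\exp\{w^\top \tanh(V h_j)\}}{\sum_q \exp\{w^\top \tanh(V h_q)\}},
\qquad z = \sum_j a_j h_j,$$

and a logistic classifier on the pooled embedding gives the bag score
$P = \sigma(w_c^\top z)$. The pre-softmax attention scores
$\mathrm{atts}_j = w^\top \tanh(V h_j)$ double as read-level evidence: Platt
scaling with two learned scalars maps them to read probabilities
$f_j = \sigma(\alpha\,\mathrm{atts}_j + \beta)$.

Read probabilities are pooled into the reported site probability with a
**rank-weighted Noisy-OR**. Plain Noisy-OR,
$F = 1 - \prod_j (1 - f_j)$, saturates at deep sites: with 200 reads of
$f_j = 0.1$ it is numerically 1, which is why depth-thresholded callers
discard low-coverage loci rather than score everything. The weighted
variant

$$F = 1 - \prod_j (1 - f_j)^{w_j}, \qquad \textstyle\sum_j w_j = 1$$

derives its exponents from the *ranks* of the read probabilities: ranks
$0..k{-}1$ (ascending, ties broken by read index) are normalized to
$u_j \in [0,1]$ and scored by the two-peaked bump
$S(u) = N(u;0,0.1) + N(u;1,0.1)$ (Gaussian densities), then normalized
within the bag. The most and least modified-looking reads dominate; a read
ranked in the middle of a bag of 5 or more receives weight below $10^{-3}$.
`F` is permutation invariant, lies in $[0,1]$, is nondecreasing in every
$f_j$, and no longer drifts to 1 with depth, so sites with 3 reads and
sites with 300 are scored on the same footing. A bag with a single read has
no rank structure; by convention $w = (1)$ and $F = f_1$.

### Positive-unlabeled training

Only a fraction of truly modified sites carry a positive label (the *label
frequency*). Each epoch the model scores every unlabeled bag with $F$ and
takes the $|P|$ lowest-scoring ones as *reliable negatives* $R$, making the
classification problem balanced ($|R| = |P|$, asserted every epoch). Two
losses are summed, $L = L_m + L_p$:

* $L_m$: Bernoulli negative log-likelihood of the classifier head $P$ over
  the labeled positives ($y=1$) and current reliable negatives ($y=0$) —
  the only labels available in PU mode;
* $L_p$: Bernoulli negative log-likelihood of the pooled $F$ over the same
  bags, plus the penalty $\lambda(\alpha^2+\beta^2)$ that keeps the Platt
  calibration from overfitting.

Both losses see the same bag sets each step; the rank-derived exponents
$w_j$ are recomputed every forward pass but treated as constants in the
backward pass (ranking is not differentiable). Optimization is mini-batch
Adam; all gradients are derived analytically and checked against finite
differences in the test suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `hidden_dim` (M) | 16 | embedding width |
| `attention_dim` (L) | 8 | attention bottleneck |
| `learning_rate` | 1e-3 (generic), 3e-3 (m6A) | Adam step size |
| `epochs` | 40 (generic), 300 (m6A) | passes over the training bags |
| `lambda` | 1e-3 | Platt penalty weight |
| `weight_decay` | 1e-3 (generic), 0.1 (m6A) | decoupled decay on weight matrices |
| `epsilon_clip` | 1e-7 | probability clip inside logs and exponents |
| `pooling` | weighted_noisy_or | bag-probability variant (`noisy_or`, `mean`, `max` for ablations) |
| `attention` | gated_tanh | `none` replaces attention with uniform 1/k weights (mean pooling) |
| `read_subsample` | 20 (generic), 15 (m6A) | per-epoch cap on reads per training bag |
| `relneg_burnin` | 0 (generic), 50 (m6A) | epochs of random provisional negatives |
| `n_restarts` | 1 (generic), 4 (m6A) | independent runs; best kept by PU validation AUC |

`m6a_train_config()` bundles the m6A defaults; `train_config()` is the
generic surface. The numbers in the m6A column were fixed on synthetic data
while designing the trainer and are the package's declared operating point,
not per-dataset tuning knobs.

## Desk-scale training choices

The original setting trains on transcriptome-scale data where overfitting
individual sites is impossible. At the scale this package targets in its
tests and examples (a few hundred sites), four choices matter and are worth
stating explicitly:

1. **Per-site baseline correction** (`bag_normalize = "signal_quartile"`).
   The absolute current level at a base is dominated by its local sequence
   context (different 5-mers differ by several pA — more than the
   modification shift itself), and the 40-feature schema does not include
   the kmer identity. Subtracting, per site, the lower quartile of each
   signal median/mean column re-expresses every read as a deviation from
   the site's baseline. The lower quartile (not the median) estimates the
   *unmodified* level as long as stoichiometry stays below roughly 0.75,
   which keeps the bag-level mean shift visible. The correction is stored
   in the checkpoint and applied identically at prediction time.
2. **Per-epoch read subsampling** (`read_subsample`). Training every epoch
   on a fresh random subset of each bag's reads prevents the network from
   memorizing bags through read-level noise — with a few hundred bags and
   ~10^3 parameters that otherwise happens quickly. Scoring and prediction
   always use all reads.
3. **Reliable-negative burn-in** (`relneg_burnin`). Lowest-$F$ selection by
   a freshly initialized model ranks the unlabeled bags arbitrarily, and
   gradient descent happily makes those arbitrary picks self-consistent
   (classic self-training confirmation bias). For the first burn-in epochs
   the provisional negatives are instead a fresh uniform draw of unlabeled
   bags each epoch: contamination then averages out as label noise while
   the consistent structure of the labeled positives accumulates, and
   lowest-$F$ selection takes over once the model is warm.
4. **Restart selection by PU validation AUC** (`n_restarts`,
   `val_fraction`). The PU bootstrap occasionally still converges to a
   poor solution. Training loss cannot tell (a collapsed run fits its own
   wrong negative picks *better* than a good run fits genuinely ambiguous
   bags), so a quarter of the labeled positives is held out and each
   restart is scored by how well it ranks them above the unlabeled bags —
   the standard label-free proxy for PU discrimination. Everything used
   for selection comes from training-side data only.

## What the synthetic generators emulate — and what they do not

`gen_m6a_dataset()` produces transcripts, RRACH candidate sites, and
per-read events: per-base raw-current samples with geometric dwell (mean 8
samples/base) around a per-5-mer baseline drawn once per kmer from
N(85, 8) pA (a seeded stand-in pore model), within-read noise of
`signal_sd = 2.5` pA, and per-base call records with ~1% deletions, ~2%
insertion flags and ~1% mismatches at quality ~30. A modified read shifts
its center-base current mean by `signal_shift_sd` × `signal_sd` and, with
probability `error_inflation`, mismatches the center base at degraded
quality. Site stoichiometry controls the fraction of modified reads, with
at least one per modified site so the OR assumption holds by construction.

This emulates the *consequences* m6A has in real data — a current-level
shift plus error inflation at the motif center, diluted by stoichiometry —
but not pore physics: no hairpin artifacts, no context-dependent dwell, no
basecaller-specific error structure, no alignment ambiguity around
homopolymers, and kmer baselines are a random table rather than a real pore
model. Passing the parameter-recovery tests therefore shows the estimator
recovers planted signal under the stated noise model; it does not certify
accuracy on real flow-cell data, for which the published benchmarks remain
the reference.

`gen_mil_bags()` is the generic counterpart (Gaussian instances, a
mean-shifted positive population along the first coordinate) used to test
the PU-MIL machinery independent of the sequencing front end.

## Numerical choices and degenerate inputs

* Probabilities are clipped at `epsilon_clip = 1e-7` before logs and before
  the `(1-f)^w` exponentiation; softmax subtracts the max score first.
* Ranking ties break by read index (stable), making weights, losses and
  reliable-negative sets deterministic; reliable-negative score ties break
  by bag id.
* `k = 1` bags take `w = (1)` (the normalized rank 0/0 is undefined).
* Deleted bases emit the sentinel feature block (0, 0, 0, 0) and quality 0
  with the deletion flag set; a read deleted at all five positions keeps
  its center base.
* Population (not sample) SD for the signal spread feature, matching
  event-level summaries of resquiggle tooling.
* Glorot-uniform initialization under the run seed; Platt starts at
  α = 1, β = 0; α is left unconstrained in sign and converges positive on
  synthetic data.
* All randomness (initialization, masking, folds, subsampling, burn-in
  draws) flows from explicit integer seeds; two runs with the same config
  are bit-identical.

## Evaluation

Bag-level metrics score the pooled site probability $F(B)$ against site
truth; instance-level metrics score the Platt read probabilities $f_j$
against read truth (available for synthetic data). ROC AUC is the
tie-averaged rank statistic; PR AUC is average precision over recall steps;
both are tested against exhaustive brute-force oracles. Coverage-stratified
evaluation (≥3 / ≥5 / ≥20 reads) re-applies the bag builder's filter so the
evaluated site sets are identical to the pipeline's. The default
classification threshold for precision/recall/F1 is 0.5.

The package's benchmark protocol at desk scale — used by its acceptance
script — generates ~200 sites (70 transcripts × 300 nt), depth U(10, 30),
stoichiometry 0.5, a 2-SD current shift with 0.2 error inflation, masks
labels at 10–50% label frequency, holds out one stratified fold, trains
with `m6a_train_config()`, and reports held-out bag- and instance-level
ROC/PR AUC averaged over three seeds, alongside a matched null data set
(shift and error inflation both 0) where AUC stays at chance. The ablation
study repeats the protocol at a 0.5-SD shift over five seeds with the
weighted Noisy-OR layer swapped for the standard one. At this desk scale
and signal strength the two pooling variants are statistically
indistinguishable (per-seed held-out AUC spreads of ~0.13 dominate mean
differences of ~0.02, with restart selection the main noise source); the
weighted pooling's designed advantage is depth invariance — stable scores
from 3-read and 300-read sites alike — not a higher mean AUC on
uniformly shallow synthetic data.

## Known limitations

* The front end consumes eventalign-like and sam2tsv-like tables; it does
  not parse FAST5/POD5, run basecalling, re-squiggle or alignment.
* Transcript-space, forward-strand coordinates only; no genomic liftover.
* Variable bag sizes are handled by per-bag forward passes, trading
  throughput for simplicity; the implementation targets desk-scale data,
  not transcriptome-scale training.
* Instance-level recovery is intrinsically weaker than site-level recovery:
  the PU objective constrains the extremes of each bag's read ranking, so
  mid-ranked reads receive little gradient.
* The stand-in pore model means absolute feature values are not comparable
  to real nanopolish/Tombo output; only the pipeline contracts are.
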