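---
title: "Sparse-representation discriminative metric learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-representation discriminative metric learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdml)
```

## The problem

Content-based image retrieval (CBIR) ranks a database of images by similarity
to a query. For brain MRI slices and similar medical images, raw feature
distances are a poor proxy for diagnostic similarity: images of the same tumor
type vary widely in shape, size and texture, while visually similar slices may
belong to different classes. `srdml` addresses this by learning *jointly*:

* a **dictionary** $B \in \mathbb{R}^{d \times K}$ with unit-norm columns
  (atoms), under which each image's feature vector $x_i$ is approximated as
  $B y_i$;
* the **coding coefficients** $Y = [y_1, \dots, y_n] \in \mathbb{R}^{K\times n}$,
  the representation in which similarity is actually measured; and
* a positive semidefinite **Mahalanobis metric** $M \in \mathbb{R}^{K\times K}$
  over the codes, $d_M^2(y_i, y_j) = (y_i - y_j)^\top M (y_i - y_j)$.

Retrieval then ranks database images by $d_M^2$ between their training codes
and the query's code.

## The joint objective

Training minimizes

$$
\min_{M \succeq 0,\; \|b_k\|_2 = 1,\; Y}\;
\underbrace{\|X - BY\|_F^2}_{\text{fidelity}}
+ \alpha \underbrace{\operatorname{Tr}(Y^\top L Y)}_{\text{atom locality}}
+ \beta \underbrace{\sum_{(i,j)} g\!\big(1 - \ell_{ij}(\tau - d_M^2(y_i,y_j))\big)}_{\text{pairwise margin}}
+ \gamma \|Y\|_F^2 .
$$

**Atom locality.** $L = W - P$ is the graph Laplacian of a $k$-NN similarity
graph over dictionary atoms, $P_{ij} = \exp(-\|b_i - b_j\|^2/\mu)$ for $b_j$
among the $k$ nearest atoms of $b_i$ (self excluded), symmetrized with the
elementwise maximum so that the union of the directed neighborhoods is kept
and $L$ is a valid (PSD, zero-row-sum) Laplacian.
$\operatorname{Tr}(Y^\top LY) = \tfrac12\sum_{ij}P_{ij}\|Y_{i\cdot}-Y_{j\cdot}\|^2$
ties the coefficient profiles of nearby atoms together. Because $L$ is
$K \times K$, the quadratic form necessarily acts on rows of $Y$ (per-atom
coefficient profiles); this is the only dimensionally consistent reading.

**Pairwise margin.** Pairs $(i, j)$ carry $\ell_{ij} = +1$ when labels agree
and $-1$ otherwise. With two thresholds $\sigma_1 = \tau - 1$ and
$\sigma_2 = \tau + 1$, the constraint
$\ell_{ij}(\tau - d_M^2(y_i, y_j)) > 1$ asks similar pairs to sit below
$\sigma_1$ and dissimilar pairs above $\sigma_2$. Violations are charged
through the generalized logistic (softplus) loss
$g(y) = \tfrac1\theta \log(1 + e^{\theta y})$, a smooth upper bound of the
hinge with sharpness $\theta$ (default 1, the reference setting).

## Alternating optimization

After K-SVD initialization of $(B, Y)$ and $M = I$, each outer iteration
updates the three blocks in turn.

**Dictionary (closed form).** Minimizing $\|X - BY\|_F^2$ without the norm
constraint gives $B_0 = XY^\top (YY^\top)^{-1}$ (a small ridge
$10^{-8}\operatorname{tr}(YY^\top)/K$ is added when $YY^\top$ is
near-singular, with a warning). Each column is then normalized and the
corresponding row of $Y$ rescaled by the same factor — an exact
reparameterization that leaves the product $BY$, and hence the fidelity term,
unchanged. We chose this over solving the Lagrange dual of the
norm-constrained problem: the reparameterized optimum attains the
unconstrained minimum, which is at least as good, with no inner solver. The
atom graph and its Laplacian are rebuilt from the new dictionary inside every
outer iteration. Because the rescaling of $Y$'s rows also perturbs the
locality/ridge/pairwise terms, the dictionary update and graph rebuild are
accepted *as one proposal* only if the joint objective does not increase;
otherwise the previous $(B, L, Y)$ is kept for this iteration.

**Coefficients (closed form per column).** With the logistic weights
$w_{ij} = g'(\Lambda_{ij})$, $\Lambda_{ij} = 1 - \ell_{ij}(\tau - d_M^2)$,
frozen at the sweep's starting iterate (a
majorization-style inner linearization), the per-column stationary condition
is the linear system

$$
\big(B^\top B + \gamma I + \alpha L + \beta \textstyle\sum_j w_{ij}\ell_{ij} M\big)\, y_i
= B^\top x_i + \beta M \textstyle\sum_j w_{ij}\ell_{ij}\, y_j ,
$$

solved for $i = 1, \dots, n$ in ascending order with freshly updated columns
used within the sweep (Gauss–Seidel; faster coupling propagation than a
Jacobi sweep). With $\alpha = \beta = 0$ this is exactly ridge regression on
the dictionary. Two numerical caveats shaped the implementation:

* Each pair appears once in the loss, so the stationary condition carries the
  weight $\beta$ (all gradient terms share a factor 2 that cancels).
* When dissimilar-pair repulsion dominates, the system matrix can be
  indefinite and its "solution" is a saddle rather than a minimizer. The
  joint objective is column-separable given the other columns, so every
  column update is safeguarded on its exact objective contribution: a column
  whose update would increase it is damped toward its previous value (up to
  six halvings) and reverted if damping fails. A final sweep-level check with
  the same damping applies the guarantee to the full objective.

**Metric (projected gradient).** The metric block minimizes
$\beta \sum g(\Lambda_{ij}) + \eta \|M - I\|_F^2$; the regularizer (weight
$\eta$, default 1, a parameter distinct from the coefficient ridge) keeps the
metric anchored at the identity. Its gradient is
$\beta \sum w_{ij}\, \ell_{ij} (y_i - y_j)(y_i - y_j)^\top + 2\eta(M - I)$,
the only form consistent with differentiating the block objective. Steps
$M \leftarrow \Pi\big(M - \xi\,\nabla\big)$ use the projection $\Pi$ onto the
feasible set — symmetrize, clip negative eigenvalues, keep the `m_rank`
largest — with the input projected first so iterates stay feasible. The
learning rate $\xi$ (default $10^{-3}$) is halved up to 20 times until
neither the block objective nor the pairwise term alone increases; the extra
condition matters because the $\eta$-regularizer is not part of the joint
objective, so descent of the block objective by itself would not guarantee
descent of the joint objective. If no step is accepted the previous
(projected) metric is returned with a warning.

By construction every accepted block move is non-increasing, so the recorded
objective trace is monotone; training stops early after `patience` (default
3) consecutive iterations with relative decrease below `tol`
(default $10^{-6}$), up to `T_max` (default 50) iterations.

**Queries.** Test images carry no labels or pairs, so they are coded by the
$\gamma$-regularized ridge solution
$y = (B^\top B + \gamma I)^{-1} B^\top x$ — the training update with the
locality and pairwise terms switched off, which makes a training column's
query code coincide with its $\alpha = \beta = 0$ training code. This is the
canonical choice; the alternative of carrying the locality term into query
coding changes codes negligibly at the default $\alpha$ and was not pursued.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `alpha` | locality weight | 0.1 | reference grid $\{10^{-3},\dots,10\}$ |
| `beta` | pairwise weight | 0.1 | same grid |
| `gamma` | coefficient ridge | 0.01 | same grid |
| `tau` | pairwise threshold center | auto | $1 +$ median identity-metric $d^2$ over similar pairs at initialization, so similar pairs start on their margin; dimensionless in code-space units |
| `theta` | softplus sharpness | 1 | reference setting |
| `k_nn` | atom-graph neighbors | 7 | best reported grid value of $\{3,5,\dots,13\}$ |
| `mu` | graph bandwidth | auto | median squared neighbor distance |
| `m_rank` | metric rank bound | $K$ | reference grid $\{50,\dots,500\}$ at full scale |
| `eta` | $\|M-I\|^2$ weight | 1 | metric-block regularizer |
| `xi` | metric learning rate | $10^{-3}$ | backtracked, so only an upper bound |
| `K` | dictionary size | $n$ | reference protocol ties it to the training-set size |

K-SVD initialization uses `max(1, round(K/20))` nonzeros per column and 10
iterations by default; atoms start as seeded random unit vectors, unused
atoms are replaced by the worst-reconstructed training column, and an
iteration that increases the reconstruction error is reverted (K-SVD with OMP
re-coding is not intrinsically monotone).

## GIST features

The feature pipeline is a standard spatial-envelope descriptor: resize to
$128 \times 128$, rescale to $[0,1]$, local contrast normalization (subtract
a low-pass component with cutoff 4 cycles/image, divide by a local
standard-deviation envelope from the same filter), then a frequency-domain
Gabor bank of 4 scales $\times$ 8 orientations whose energy images are
average-pooled on a $4\times4$ grid — $4 \cdot 8 \cdot 16 = 512$ dimensions.
Radial centers fall off geometrically (factor 1.85 from 0.3 cycles/pixel) and
each transfer function is peak-normalized. Descriptors are L2-normalized by
default (a switch), which stabilizes the balance between the fidelity term
and the regularizers. The construction is the canonical one behind published
512-dimensional GIST features; exact numeric equality with any particular
reference implementation is not claimed.

## Synthetic data: what it emulates, and what it does not

`generate_synthetic()` plants the structure the model assumes: $K$ random
unit atoms, one disjoint (or partially overlapping) atom support per class,
nonnegative coefficient magnitudes $|N(1, 0.25)|$ — nonnegativity avoids
sign-cancellation flakiness in recovery checks — and i.i.d. Gaussian feature
noise. Defaults (3 classes $\times$ 60 images, 64 dimensions) mirror a
three-class tumor-type setting at desk scale. Passing tests on this generator
demonstrates that the optimization recovers planted structure and that the
retrieval pipeline is correct; it does *not* demonstrate performance on real
MRI features, whose classes are not exact unions of sparse subspaces, whose
noise is not i.i.d. Gaussian, and whose class geometry is far less separable.

The test fixtures are: `tiny` (6-dim, 2 classes of 4 — fast descent checks),
`separable3` (3 classes, disjoint supports, $\sigma = 0.01$) and `noisy3`
($\sigma = 0.1$). Cross-validation fixtures train with `T_max = 12`, 5 K-SVD
iterations and 2000 balanced pairwise constraints — problem sizes chosen so a
full 5-fold run completes in seconds to minutes on one CPU while leaving the
qualitative behavior (near-perfect retrieval on separable data, monotone
degradation with noise) unchanged.

## Numerical choices and degenerate inputs

* Ties in atom-neighbor selection and in retrieval ranking break by ascending
  index (stable, deterministic).
* Duplicate atoms get graph weight $\exp(0) = 1$; a zero-variance (constant)
  image yields an all-zero preprocessed image and hence a zero descriptor.
* Singular systems (coding, dictionary) receive a $10^{-8}$-scale ridge with
  a warning rather than failing.
* Single-class training sets disable the pairwise term with a warning
  ($\beta = 0$); queries with no relevant database item are skipped in mAP
  with a warning.
* All randomness (K-SVD start, pair sampling, fold assignment, generators) is
  seeded through function arguments; fits with the same seed are bit-identical
  on one platform, and model containers are persisted uncompressed so
  identical fits serialize to identical bytes.
* `m_rank` truncation conflicts with the $\|M - I\|^2$ anchor when
  `m_rank` < $K$ (the identity is then infeasible); the update therefore
  measures descent from the *projected* input. At the default `m_rank` = $K$
  the projection is a no-op.

## Known limitations

* The alternating scheme guarantees monotone descent, not global optimality;
  different seeds reach different local minima (the recovery test's
  sign/permutation matching reflects the inherent invariances).
* The frozen-weight coefficient step is conservative under strong
  dissimilar-pair repulsion (columns fall back to damped moves), trading
  per-sweep progress for a descent guarantee.
* Dictionary size $K = n$ (the reference protocol) makes training cost grow
  as $n \cdot K^3$ per sweep; for thousands of images set `K` explicitly.
* The pairwise term uses a sampled constraint set when `n_pairs` is finite;
  extremely unbalanced classes may leave some images with few constraints.
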