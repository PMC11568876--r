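---
title: "Kernel and functional neural networks for genetic data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel and functional neural networks for genetic data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gennet)
```

# The kernel neural network

## Model

For $n$ individuals with phenotype $y$, fixed-effect design $Z$ (intercept,
age, sex, ...) and genotype matrix $X$ ($n \times p$ allele counts), the
kernel neural network (KNN) is the hierarchical Gaussian model

$$
\begin{aligned}
y \mid Z, a &\sim \mathcal N_n(Z\beta + a,\ \phi I_n),\\
a \mid u_1,\dots,u_m &\sim \mathcal N_n\Big(0,\ \textstyle\sum_{j=1}^J \tau_j H_j(U)\Big),\\
u_1,\dots,u_m &\sim \mathcal N_n\Big(0,\ \textstyle\sum_{l=1}^L \xi_l K_l(X)\Big),
\end{aligned}
$$

where the $K_l(X)$ are input kernel matrices built from the markers — the
product kernel $K = XX^\top/p$ (the genetic relationship matrix), a Gaussian
kernel, or a polynomial kernel — and each hidden kernel $H_j$ is a polynomial
kernel of the latent $n \times m$ hidden-unit matrix $U$,
$H_{ij} = (u_i \cdot u_j / m + c)^d$ with $u_i$ the $i$-th row. The structure
mirrors a neural network whose inputs and hidden units are kernel matrices:
the nonlinearity of the hidden kernel lets the genetic covariance pick up
non-additive (e.g. interaction) signal while the number of parameters stays
tiny.

## Expansion into a linear component basis

Marginally, $\operatorname{Var}(a) = \sum_j \tau_j\, \mathbb E[H_j(U)]$, and
for polynomial hidden kernels of degree 1 and 2 the expectation is available
in closed form. With $K_u = \sum_l \xi_l K_l$:

* degree 1: $\mathbb E[H]_{ij} = (K_u)_{ij} + c$;
* degree 2 (Gaussian fourth moments, Isserlis' theorem):
  $\mathbb E[H]_{ij} = ((K_u)_{ij} + c)^2 +
  \big((K_u)_{ii}(K_u)_{jj} + (K_u)_{ij}^2\big)/m$.

The $1/m$ division in $H$ makes the expectation stable in the number of
hidden units. Substituting $K_u$ and collecting powers of the $\xi_l$ turns
the marginal covariance of $y$ into a *linear* combination
$\sum_r \theta_r V_r + \phi I$ of known matrices: the $K_l$ themselves for
degree 1; for degree 2, per kernel pair $(l, l')$ the matrix
$(1 + 1/m)\, K_l \circ K_{l'} + (d_l d_{l'}^\top + d_{l'} d_l^\top)/(2m)$
(with $d_l = \operatorname{diag}(K_l)$ and $\circ$ the entrywise product),
plus the input kernels and the all-ones matrix when the offset $c \neq 0$.
`expand_components()` produces exactly this basis. The package estimates the
free coefficients $\theta_r$ and never inverts back to $(\tau, \xi)$:
prediction only needs $\sum_r \hat\theta_r V_r$, and the map
$(\tau,\xi) \mapsto \theta$ is many-to-one. A simulation test confirms that
the empirical covariance of phenotypes drawn from the exact hierarchy matches
this expansion entrywise for both degrees, and the closed form is guarded by
a Monte-Carlo oracle.

## MINQUE estimation

Variance components are estimated by minimum norm quadratic unbiased
estimation: with working covariance $V_w = \sum_r w_r V_r$ and
$R = V_w^{-1} - V_w^{-1} Z (Z^\top V_w^{-1} Z)^{-1} Z^\top V_w^{-1}$, solve

$$ S\theta = q, \qquad S_{rs} = \operatorname{tr}(R V_r R V_s), \qquad
   q_r = y^\top R V_r R y. $$

MINQUE(0) ($V_w = I$) supplies initial values; iterative MINQUE re-solves
with $w = \hat\theta$ (truncated at zero, residual weight floored at
$10^{-6}\operatorname{var}(y)$ to keep $V_w$ invertible) until the maximum
relative change drops below `tol` ($10^{-4}$, at most 20 iterations — the
iteration typically stabilizes within ten). Unbiasedness needs only
$\operatorname{Var}(y)$, not Gaussianity, which is why binary phenotypes can
be fitted on the observed 0/1 scale (a linear-probability mixed model) and
scored by misclassification and AUC; no liability-threshold link is
attempted. Numerical policies: a singular $S$ falls back to a pseudo-inverse
solve, a singular $V_w$ receives a ridge bump of
$10^{-8}\operatorname{tr}(V_w)/n$, and both events are logged in `fit_meta`.
MINQUE may return negative $\hat\theta_r$; raw values are reported, and
negatives are truncated to zero for prediction and for iteration weights.

Prediction for new samples is BLUP under the fitted covariance:
$\hat y = Z_\ast\hat\beta + \big(\sum_r \hat\theta_r V_r^{\rm cross}\big)
\big(\sum_r \hat\theta_r V_r + \hat\phi I\big)^{-1}(y - Z\hat\beta)$, where
the cross components are the test-by-train blocks of the same expansion
(`expand_cross_components()`; the residual identity does not transfer). With
a single kernel this is exactly kernel ridge regression with ridge
$\hat\phi/\hat\tau$, which the tests assert at machine precision.

## Batch training

For large cohorts the samples are partitioned into $B$ balanced random
batches, the model is fitted independently on each batch's sub-kernels, and
the variance-component and fixed-effect estimates are averaged unweighted
(batch sizes differ by at most one, so weighting is immaterial). $B = 1$
reproduces the unbatched fit bit for bit. Averaging estimates, not
predictions, is the default; per-batch prediction averaging is available via
`predict_knn_batched(mode = "predictions")`. Prediction after a batched fit
uses cross-kernels against *all* training samples, which maximizes
information at predict time. The batched estimator inherits unbiasedness
from the per-batch estimator, which the acceptance suite checks at $n = 600$,
$B \in \{2, 5, 10\}$ over 100 replicates.

# The functional neural network

## Model

For candidate-gene analysis the $p$ markers of a region are treated as
noisy evaluations of a smooth genotype function $G(t)$ of genomic position
($t$ = base-pair position min–max scaled to $[0,1]$). Each sample's dosage
profile is projected onto a clamped B-spline basis (order 4 by default) by
roughness-penalized least squares; missing dosages are simply omitted from
the sum, so neighbouring markers fill the gap. Layers map functions to
functions: layer $d$ computes

$$ x^{(d+1)}(s) = \sigma\Big( \alpha_0^{(d)}(s) +
   \int \alpha^{(d)}(s, t)\, x^{(d)}(t)\, dt \ (+\ \gamma^\top Z \text{ at
   the first layer}) \Big), $$

with the intercept function $\alpha_0^{(d)}$ on the outgoing basis and the
weight surface $\alpha^{(d)}$ on the tensor of the outgoing and incoming
bases. For a scalar phenotype the head is
$\hat y = \alpha_0^{(D)} + \int \alpha^{(D)}(t)\, x^{(D)}(t)\, dt$ with
scalar $\alpha_0^{(D)}$ and univariate $\alpha^{(D)}$; a vector-phenotype
head (univariate $\alpha_0^{(D)}$, bivariate $\alpha^{(D)}$) is outside the
supported surface of this release. In basis coefficients every layer is
$u = b_0 + W J c$ with $J$ the incoming basis Gram matrix; the activation
(default `tanh`; `relu` and `identity` selectable — the reference protocol
does not name $\sigma$) is applied on a per-interval Gauss–Legendre grid and
re-projected to the outgoing basis. With `order` nodes per knot interval the
quadrature integrates all basis-product polynomials exactly, so the
projection and all Gram/penalty matrices carry no quadrature error; the
identity-activation reduction to the functional linear model is verified at
$10^{-6}$ against dense independent quadrature.

## Loss, penalty and training

The loss is mean squared error (continuous) or mean cross-entropy with a
logistic link (binary), plus a roughness penalty
$\lambda \sum_d \big[\int (\alpha_0^{(d)\prime\prime})^2 +
\iint (\partial_t^2 \alpha^{(d)})^2 + (\partial_s^2 \alpha^{(d)})^2\big]
+ \lambda \int (\alpha^{(D)\prime\prime})^2$, computed exactly from
second-derivative Gram matrices. Affine functions are penalty-free
(null space of the second derivative), tested exactly. One shared $\lambda$
is used across all layers and functions, selected on validation data loss
over a log-spaced grid (default $10^{-4}\dots10$, 6 points); training is
full-batch Adam (defaults $\mathrm{lr} = 10^{-3}$,
$\beta = (0.9, 0.999)$; the reference protocol is order-4 bases, hidden
layers with 100 and 50 interior knots — "knots" is read as interior-knot
counts, with the basis dimension = knots + order — and 10 000 epochs; the
package tests run far smaller configurations). Initialization is
i.i.d. $\mathcal N(0, 1/\mathrm{fan_{in}})$ from a seed; a non-finite loss
triggers one restart at half the learning rate, then an abort. Two runs with
the same (seed, grid, epochs) are bit-identical.

Three conditioning choices, made after diagnosing optimization failures on
simulated data and all leaving the model class unchanged:

1. **Variance-calibrated initialization.** Integral-operator layers shrink
   between-sample signal by roughly an order of magnitude each (the Gram
   matrices have $O(1/\dim)$ entries), so with plain $1/\mathrm{fan_{in}}$
   init the head would need weights $\sim 10^3$ that Adam cannot reach in
   any reasonable epoch budget. At initialization each layer is rescaled so
   its pre-activations have unit between-sample standard deviation on the
   training curves, and the head toward unit output spread
   (layer-sequential unit-variance initialization). `fnn_train(calibrate =
   FALSE)` disables it.
2. **Dimensionless penalty.** Raw second-derivative integrals scale like
   (knot spacing)$^{-4}$ and reach $10^7$ for realistic bases, so a fixed
   $\lambda$ grid would be architecture-dependent. The shared $\lambda$
   multiplies the penalty normalized by its value at the calibrated
   initialization (a single scalar for the whole network).
3. **Input/response standardization in `fit_fnn()`.** Curves are
   functionally centered (training mean curve subtracted) and divided by one
   global scale (root mean squared $L_2$ norm); a continuous response is
   standardized and predictions mapped back (`predict_fnn_fit()`). Without
   centering, the common genotype offset saturates `tanh` while the
   between-sample signal sits in the fourth-order tail of the loss.

# The synthetic-data generators

`sim_genotypes()` draws two latent Gaussian haplotype vectors per individual
with AR(1) correlation `ld_rho` along the chromosome and thresholds them at
the MAF quantile, giving Hardy–Weinberg-consistent diploid dosages with
plausible LD; MAFs are uniform on `maf_range`, positions equally spaced with
jitter. It emulates SNP-array input at candidate-gene to small-cohort scale;
it does not model demography, coalescent structure, imputation uncertainty,
or long-range LD, so passing tests speak to estimator correctness under the
stated model, not to robustness against those real-data features.

`sim_knn_phenotype()` draws *exactly* from the three-level hierarchy
(hidden units, polynomial hidden kernel, genetic effect, residual), which is
what lets a single property couple three modules: the empirical covariance
over replicates must match `expand_components()`'s analytic expansion.
`sim_fnn_phenotype()` provides a linear functional signal
($\langle \sin(2\pi t), G\rangle$), a purely non-additive interaction (the
product of *centered* regional burdens — centering removes the additive
component a linear model could exploit), and a nonlinear burden signal
($\sin$ of a standardized burden); noise is scaled to a requested
signal-to-noise variance ratio.

Study conditions fixed for the FNN-vs-FLM comparison: $n = 500$ (400
training, of which 80 validation; 100 test), two 20-SNP regions,
$\mathrm{snr} = 2$ (an $R^2$ ceiling of $2/3$ — strong but plausible for a
demonstration region), hidden layers (6, 4) knots, 1500 epochs at
$\mathrm{lr} = 0.02$, $\lambda \in \{10^{-4}, 10^{-2}\}$. Problem sizes in
the acceptance suite ($n = 500$/100 replicates for recovery, $n = 600$ for
batching, $10^5$ Monte-Carlo draws on 50 instances) are the package's chosen
desk-scale study sizes.

# Numerical and format conventions

* Dosages count copies of the A1 (bim first) allele: bed codes
  00 → 2, 10 → 1, 11 → 0, 01 → missing. The text (ped/map) format does not
  store the counted allele, so the reader infers A1 as the empirical minor
  allele with a lexicographic tie-break.
* Missing genotypes are mean-imputed per variant immediately before kernel
  construction (GCTA-compatible); the FNN instead omits missing dosages from
  the smoothing sum.
* The GRM triangle is stored row-major $i \ge j$ in single precision with
  the GCTA file triple; round trips are exact at float32.
* The product kernel defaults to raw $XX^\top/p$ (matching the printed
  definition); GCTA-style column standardization is a flag, with statistics
  always taken from the training set. Kernels are not double-centered before
  MINQUE (config toggle deliberately absent from the default path).
* The Gaussian kernel divides squared distance by $\mathrm{bandwidth}
  \times p$, so the bandwidth is dimensionless in the number of markers.
* Ties in classification break toward the positive class; AUC uses
  mid-ranks (ties count one half); MSE uses the population denominator.

# Known limitations

* Degree > 2 hidden kernels have no closed-form expectation here; only the
  explicit Monte-Carlo path (`mc_hidden_kernel()`) supports them.
* Recovery of $(\tau, \xi)$ from the expanded coefficients is out of scope,
  as are standard errors and tests on variance components.
* The FNN is a candidate-gene tool; it is not designed for genome-wide
  input, and only the scalar-phenotype head is supported.
* Binary phenotypes use the linear-probability Gaussian machinery; no
  class-imbalance handling is provided.
* PLINK dosage (non-integer) formats, VCF/BGEN, and chunked streaming of
  biobank-scale bed files are not supported.
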