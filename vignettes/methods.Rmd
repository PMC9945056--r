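---
title: "Multi-sample spatial clustering with hidden Markov random fields: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sample spatial clustering with hidden Markov random fields: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smirf)
```

# The problem

Spatially resolved transcriptomics (SRT) experiments routinely produce
several tissue sections ("slides"), each a set of spots with a 2-D position
and an expression profile. Two things are wanted simultaneously: cell/domain
clusters that are *spatially coherent* within each slide and *shared* across
slides, and an alignment of the slides that removes slide-level (batch)
technical variation. Doing these sequentially — integrate first, cluster
after — lets neither step see the other's structure; `smirf` fits one model
that does both at once, on low-dimensional embeddings (top principal
components) of the expression matrix.

# The model

For slide $t = 1, \dots, T$ and spot $i$ with embedding
$v_{ti} \in \mathbb{R}^q$, the embedding splits additively into a
cluster-related part and a batch-related part, $v_{ti} = z_{ti} + u_{ti}$:

$$ v_{ti} \mid y_{ti} = k,\, u_{ti} \;\sim\; \mathcal N(\mu_k + u_{ti},\, \Sigma_k), $$

with cluster means $\mu_k$ and covariances $\Sigma_k$ **shared by all
slides** — this sharing is what integrates the samples.

**Labels.** The label field $y_t$ of each slide follows a Potts model on the
spot neighbour graph $E_t$,

$$ P(y_t) \;\propto\; \exp\Big( \beta_t \sum_{(i,j) \in E_t} \mathbb 1[y_{ti} = y_{tj}] \Big), $$

rewarding equal labels on neighbouring spots. The smoothness $\beta_t \ge 0$
is per slide and estimated, so a section with crisp anatomical layers and a
section with salt-and-pepper cell mixing get different amounts of smoothing.

**Batch field.** The batch embeddings $u_{ti}$ follow an intrinsic
conditional autoregressive (CAR) model per slide:
$u_{ti} \mid u_{t,N_i} \sim \mathcal N(\bar u_{t,N_i},\, \Lambda_t / |N_i|)$
with $\bar u_{t,N_i}$ the neighbour mean and $\Lambda_t$ diagonal. This
captures smooth technical variation induced by neighbouring
microenvironments; crucially, a *constant per-slide offset costs the
intrinsic CAR nothing*, so slide-level mean shifts are absorbed by $u$
rather than distorting the cluster means. Isolated spots (QC holes) receive
the marginal prior $\mathcal N(0, \Lambda_t)$.

**Identifiability.** A global translation can move freely between
$\{\mu_k\}$ and $u$; we pin it by grand-mean-centering $u$ over *all* spots
of all slides after each update. Per-slide centering is deliberately not
used — per-slide means of $u$ *are* the batch shifts. Consequently the
fitted $\mu_k$ are identified up to one global translation (the grand mean
of the generative batch field), which is immaterial for clustering and for
aligned embeddings.

# Fitting: ICM-EM

Exact inference is intractable (the Potts partition function), so fitting
alternates iterated conditional modes (ICM) for the latents with EM-style
parameter updates, all conditioned pseudo-likelihood-wise on current hard
neighbour configurations:

1. **ICM labels** — sequential raster-order sweeps setting
   $y_{ti} \leftarrow \arg\max_k \{\log \mathcal N(v_{ti} - \hat u_{ti};
   \mu_k, \Sigma_k) + \beta_t m_{tik}\}$, where $m_{tik}$ counts neighbours
   of $i$ currently labelled $k$ (recomputed within the sweep; ties go to
   the smaller $k$). Up to `icm_sweeps` (default 10) sweeps, stopping at a
   fixed point.
2. **ICM batch field** — coordinate updates
   $\hat u_{ti} \leftarrow (\Sigma_k^{-1} + d_i \Lambda_t^{-1})^{-1}
   (\Sigma_k^{-1} (v_{ti} - \mu_k) + d_i \Lambda_t^{-1} \bar u_{ti})$,
   then grand-mean-centering. The one-spot update is a Gauss–Seidel sweep of
   a large sparse normal system; we iterate it to its fixed point (up to
   `u_sweeps` = 50 sweeps, early-stopped at `u_tol` = 1e-3 max change)
   rather than performing a single sweep per outer iteration. This matters:
   a single sweep starting near zero leaves $u$ artificially smooth, the
   roughness-based $\Lambda$ estimate below then collapses to its floor and
   freezes $u$ before it can absorb the slide shifts.
3. **E step** — responsibilities
   $R_{tik} \propto e^{\beta_t m_{tik}}\, \mathcal N(v_{ti} - \hat u_{ti};
   \mu_k, \Sigma_k)$, log-sum-exp stabilized.
4. **M step** — responsibility-weighted means and covariances of
   $r = v - \hat u$; the intrinsic-CAR variance estimate
   $\lambda_{td} = \frac{1}{n^*_t}\sum_{i: d_i > 0} d_i\,
   \big[(\hat u_{tid} - \bar u_{tid})^2 + s^2_{tid}\big]$;
   and a grid search for each $\beta_t$ over `beta_grid` (default 0 to 4 by
   0.2, ties to the smallest value) maximizing
   $\sum_i \sum_k R_{tik} [\beta m_{tik} - \log \sum_{k'} e^{\beta m_{tik'}}]$,
   since $\beta$ has no closed form.

The $s^2_{tid}$ term is the diagonal of the Laplace-approximation posterior
variance $(\Sigma_k^{-1} + d_i \Lambda_t^{-1})^{-1}$ of $u_{ti}$ — the
expected rather than plug-in sufficient statistic. The same term is added
(responsibility-weighted) to the $\Sigma_k$ update. Both corrections are
load-bearing: with plug-in moments only, the smoothed mode field
systematically understates the CAR roughness, $\Lambda \to 0$ (frozen batch
field) or, in the opposite regime, the batch field interpolates the data
and $\Sigma \to 0$ with an unbounded likelihood. With them, variance splits
stably between the emission and the batch layer (on generator draws with
unit noise the fitted $\Sigma$ diagonals come back near 1 and $\lambda$
near its conditional scale). The plain plug-in estimators remain available
as the defaults of the exported `m_step_gaussian()` / `m_step_car()`
building blocks.

**Objective and stopping.** The tracked objective is the pseudo-log-likelihood
$\ell = \sum_{t,i} \log \sum_k p_{tik}\, \mathcal N(v_{ti} - \hat u_{ti};
\mu_k, \Sigma_k)$ with $p_{tik} = \mathrm{softmax}_k(\beta_t m_{tik})$; the
Potts partition function never appears. ICM-EM is not a strict ascent
method for this (or any single) objective: once the parameters are
essentially stationary, the interplay of the mode updates can nudge $\ell$
down by a sliver per iteration indefinitely. The loop therefore stops when
the relative change falls below `tol` (1e-6) **or** when an iteration
*decreases* $\ell$ by a small relative amount (< 1e-3), in which case the
previous — better — state is kept. Large drops (early label avalanches)
continue. In practice the trace rises steeply for 5–10 iterations and the
safeguard then terminates the fit; the reported trace is non-decreasing.

**Initialization.** Pooled k-means (hand-rolled k-means++ seeding, 10
restarts, best within-cluster sum of squares, re-seeded up to 5 times on an
empty cluster) gives initial labels; $\mu_k, \Sigma_k$ are the cluster
moments plus a `ridge` (1e-6) diagonal; $u = 0$; $\beta_t$ starts at the
smallest positive grid value; $\lambda_t$ at half the per-slide residual
variance. Everything is seeded: the fit for cluster count $K$ uses
`seed + K`, so serial and parallel (forked) multi-K runs are bit-identical.

**Model selection.** For each candidate $K$ the converged
pseudo-log-likelihood $\hat\ell_K$ enters a modified BIC,

$$ \mathrm{MBIC}_K = -2 \hat\ell_K + c\, d_K \log(n) \log(\log n), \qquad
   d_K = Kq + K\tfrac{q(q+1)}{2} + Tq + T, $$

with $c = 1$ by default; the $\log\log n$ inflation guards against
over-selection at SRT-scale $n$. The selected $K$ minimizes MBIC, ties to
the smaller $K$.

# Preprocessing and graphs

- Counts are library-size normalized to `scale` = 1e4 and
  `log1p`-transformed; spots with library size below 15 and genes expressed
  in under 1% of spots are dropped (all configurable). The 2000 most
  variable genes enter PCA.
- PCA runs on the spot-concatenated matrix of **all slides together**, with
  global (not per-slide) centering — per-slide centering would silently
  remove exactly the shifts the batch field is meant to estimate. Three
  methods: exact SVD (`classical_pca`), a randomized range-finder SVD
  (`approximate_pca`, the default; oversampling 10, two power iterations,
  seeded) and `weighted_pca`, which scales gene $g$ by $\sqrt{w_g}$ with
  `"auto"` weights equal to inverse first-pass residual variance floored at
  1e-8, down-weighting noisy genes. Component signs are fixed (largest
  loading entry positive) so every method is deterministic.
- Neighbour graphs are platform-free: by default spots within a radius of
  1.2 times the median nearest-neighbour distance are connected, which
  yields the canonical degree 4 on square lattices and 6 on hexagonal ones
  without any platform flag; a union-symmetrized kNN builder covers
  irregular platforms. Isolated spots are kept and handled by the marginal
  CAR prior.

# The synthetic generator

`simulate_multisample()` is the generative twin of the fitted model and the
substrate of the package's property checks. Per slide: a unit-spacing
square or hexagonal lattice; Potts labels from a seeded Gibbs sampler (100
sweeps); a batch field drawn from a *proper* CAR with precision
$\lambda_d^{-1}(D - \rho A)$ plus a slide-level mean shift; embeddings
$v = \mu_y + \mathcal N(0, \sigma^2 I) + u$. Cluster means sit on a regular
simplex when $q \ge K - 1$ and otherwise on a regular $K$-gon in the first
two dimensions, scaled so the *minimum* pairwise distance equals
`mu_separation` — one knob controls difficulty. An optional Poisson count
layer (`counts ~ Poisson(exp(Wv + eps))` with seeded unit-norm loadings)
exercises the count-input path.

Defaults are the package's reference study conditions: $T = 2$ slides of
$30 \times 30$ spots, $K = 4$, $q = 2$, $\beta = 1$ (just below the 4-state
Potts critical point, giving coherent but irregular domains), unit emission
noise, separation 6 (i.e. 6 noise SDs), $\lambda = 1$, $\rho = 0.9$, and a
$(+2, -2)$ shift on the second slide.

Two deliberate mismatches with the fitted model, and their consequences:
the generator samples a proper CAR with $\rho = 0.9$ because the intrinsic
CAR is improper and cannot be sampled — so the fitted $\lambda$ is a
nuisance re-expression of the proper field's scale, not an estimate of the
generative $\lambda$; and real SRT counts (zero inflation, segmentation
errors, platform-specific layouts) are *not* emulated, so passing checks
demonstrate correctness of the algorithm under its own assumptions, not
performance claims on real tissue.

# What the checks compute, at which sizes

The test-suite and the acceptance script re-derive, at desk scale chosen to
keep a full run in a couple of minutes on one core: equivalence of the
$\beta \equiv 0$, $u \equiv 0$ limit with an independently coded
equal-weight Gaussian-mixture EM ($n = 200$, agreement to 1e-6); trace
monotonicity, integrated ARI $\ge 0.95$ and a batch-spread ratio $\le 0.2$
on ten replicate draws of the reference conditions; $\beta$ recovery within
$\pm 0.4$ from single sampled fields on a $40 \times 40$ lattice; MBIC
selection of the true $K = 5$ at separation 5 on two $25 \times 25$ slides;
closed-form ARI/NMI values; CAR sample covariance against the dense inverse
precision (3-node path, 10,000 draws, 5%); Potts edge-concordance
monotonicity in $\beta$; and bit-identity of serial versus 4-worker multi-K
fits.

# Design choices on genuinely open points

- **NMI normalization**: arithmetic mean of the two entropies
  ($2I/(H_1 + H_2)$), fixed and documented; other conventions (min, max,
  geometric) differ by a few percent on unbalanced partitions.
- **Integrated metrics** pool the label vectors across slides and score
  once. Unlike averaging per-slide scores, pooling is sensitive to cluster
  identities being swapped between slides — which is precisely the
  integration failure mode worth measuring. Pooled pair-counting ARI is not
  exactly invariant under replicating a slide (its chance correction is
  size-dependent); NMI is.
- **$\Lambda_t$ diagonal**, not full: stabilizes the CAR M-step at small
  $n$ and keeps the per-spot solves trivial.
- **Pseudo-likelihood E step** conditioned on current hard neighbour
  labels, rather than a variational Potts treatment: deterministic, cheap,
  and exact in the $\beta = 0$ limit.
- **Empty clusters** keep their previous parameters with a warning rather
  than being deleted, so $K$ in the MBIC table always means "requested K";
  a persistent dead cluster simply loses to a smaller $K$ on MBIC.

# Limitations

Embeddings are taken as fixed inputs — dimension reduction is not
re-estimated jointly with clustering. The reported objective is a
pseudo-likelihood surrogate, so MBIC comparisons are internally consistent
but not calibrated against a true marginal likelihood. $\beta$ lives on a
bounded grid (default cap 4.0); label fields smoother than that saturate.
The CAR batch field can in principle absorb genuinely biological smooth
variation that is orthogonal to the cluster structure. 3-D coordinates and
multi-modal measurements are out of scope.
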