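---
title: "Bayesian inference for spectral graph models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inference for spectral graph models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative
model, the inference machinery, the synthetic-data generator that stands
in for source-localized MEG, and the numerical and design choices that a
maintainer would want spelled out.

## The spectral graph model

The SGM is a hierarchical linear model of steady-state brain oscillations
with two layers. A *mesoscopic* layer describes each region's local
excitatory and inhibitory populations; a *macroscopic* layer couples
long-range excitatory signals across the structural connectome. Because
the model is linear, its steady-state solution is available in closed form
per frequency:

$$X(\omega) = \left[\, j\omega I + \tfrac{1}{\tau_G} F_G(\omega)\,
\mathcal{L}(\alpha, v; \omega) \right]^{-1} H_{local}(\omega)\, P(\omega).$$

**Gamma kernel.** Synaptic/dendritic filtering is lumped into the gamma
impulse response $f(t) = (t/\tau^2)e^{-t/\tau}$, whose transform
$F(\omega) = (1/\tau^2)/(j\omega + 1/\tau)^2$ is a unit-gain low-pass
(`gamma_response()`). Three time constants use it: $\tau_e$, $\tau_i$
locally and $\tau_G$ for the long-range layer.

**Mesoscopic transfer function.** `local_transfer()` solves the
two-population loop in the frequency domain. With excitatory self-gain
fixed at 1, alternating gain $g_{ei}$ coupling the populations in both
directions, and inhibitory self-gain $g_{ii}$,

$$j\omega X_e = -(F_e/\tau_e) X_e - (g_{ei} F_i/\tau_e) X_i + P, \qquad
  j\omega X_i = +(g_{ei} F_e/\tau_i) X_e - (g_{ii} F_i/\tau_i) X_i + P,$$

and $H_{local} = (X_e + X_i)/P$. The closed form used in the code is the
algebraic solution of this $2\times2$ system; the test suite checks it
against a literal matrix solve at random parameter points, which keeps the
algebra honest. A structural anchor supports this construction: clearing
the gamma denominators gives a degree-6 characteristic polynomial whose
stability boundary at $g_{ei}\to 0$ is exactly $g_{ii} < 2$ — the upper
edge of the widest inhibitory-gain bound used for estimation, as it should
be if the bounds were chosen to hug the stability region.

**Complex Laplacian.** `complex_laplacian()` builds
$\mathcal{L} = I - \alpha C^*(\omega)$ where $C^*$ is the symmetric
degree-normalized connectivity ($w_{ij}/\sqrt{d_i d_j}$, degrees from the
delay-free weights) with conduction-delay phases
$e^{-j\omega d_{ij}/v}$. Distances are stored in millimetres (the
tractography convention) and converted to metres inside the model so that
$v$ is in m/s. Row-degree normalization is available as an option; the
symmetric scheme is the default because it keeps the $\omega = 0$
spectrum inside $[1-\alpha,\, 1+\alpha]$, which the tests exploit.

**Forward solver.** `forward_spectrum()` offers two algebraically
equivalent paths per frequency: a direct linear solve (default) and an
eigendecomposition of $\mathcal{L}(\omega)$. The delay phases make
$\mathcal{L}$ frequency-dependent, so the decomposition must be done per
frequency and has no amortization advantage here; the eigen path is kept
because the two paths' agreement (relative $10^{-8}$, typically
$10^{-14}$) is a strong end-to-end oracle for the linear algebra. At the
package's desk scale ($N \le 86$ regions, 40 frequencies) either path is
milliseconds.

**Stability.** `stability_check()` locates the poles of $H_{local}$
numerically as the roots of the degree-6 polynomial
$A(s)B(s) + g_{ei}^2 a^3 b^3$ (with $a = 1/\tau_e$, $b = 1/\tau_i$,
$A = s(s+a)^2 + a^3$, $B = s(s+b)^2 + g_{ii}b^3$) and requires every real
part below $-10^{-9}$. The margin keeps marginally stable points (poles
numerically on the axis) out of the accepted set.

## Observation features

`build_features()` implements the observation map $G$: the dB PSD
($20\log_{10}|X|$, floored at $10^{-20}$) is z-scored per region across
frequency; the alpha-band (8–12 Hz inclusive) summed dB power is z-scored
across regions; both are concatenated, PSD segment first in region-major
order, giving length $NF + N$ (2788 for a 68-region atlas at 40
frequencies). Two conventions are fixed and recorded in the layout tag:
z-scores use the population standard deviation (denominator $n$), and
alpha power is summed on dB values. Per-region (rather than global)
z-scoring was chosen so the PSD segment carries spectral *shape* only,
leaving spatial information to the alpha segment; because both segments
are z-scored, the features are invariant to any constant rescaling of the
underlying spectrum, which the tests assert exactly.

## Reparameterization and prior

Bounded parameters are mapped to the real line by the scaled logit
$\theta = 10\log\!\big(u/(1-u)\big)$, $u = (s - l)/(h - l)$ (natural log;
`scaled_logit()`), with the Gaussian prior $\theta \sim N(0, 100 I)$. The
inverse map lands strictly inside the box by construction, so bound
violations are impossible no matter what the density estimator emits. The
induced prior on each parameter is heavy at the interval edges — a
deliberately weak prior. Posterior densities transport between scales via
the diagonal Jacobian `log_abs_det_jacobian()`, verified against central
finite differences. For the two gains the widest bound tier
($g_{ei} \le 0.7$, $g_{ii} \le 2.0$) defines the map during simulation-based
inference; the narrower tiers exist for the annealing baseline's
sequential scheme.

## Amortized posterior estimation

`simulate_training_set()` draws $\theta_m$ from the prior, runs the
forward model on a template connectome, and adds i.i.d. Gaussian noise of
standard deviation $\sigma$ to every feature entry. The noise is not a
nuisance: without it the posterior is a near-degenerate distribution on
the forward manifold and no smooth estimator approximates it well. The
working default in this model family is $\sigma = 1.6$ (suggested range
0.8–2.0); simulations at reduced scale in this package use
$\sigma = 0.5$ with the smaller feature dimension. Failed forward draws
are resampled and counted, never silently dropped.

`train_posterior()` whitens features (per-dimension standardization, PCA
to `n_pca` unit-variance scores) and fits the conditional density
$q(\theta \mid y)$ with a **mixture density network**: one tanh hidden
layer whose outputs parameterize a $K$-component Gaussian mixture with
full covariance per component (Cholesky factors, exponential diagonal).
Training maximizes the mean conditional log-likelihood — the same proper
scoring rule used by neural posterior estimation — with Adam, minibatches,
gradient-norm clipping, and early stopping on a held-out split. The
implementation is authored in-package with hand-derived gradients; the
test suite verifies them against finite differences to $10^{-5}$ and
verifies the whole estimator against a conjugate linear-Gaussian problem
where the posterior is known in closed form. Flow-based architectures are
a drop-in alternative in principle; the mixture family was chosen because
it admits exact conditional moments (`mdn_moments()`), exact sampling, and
a transparent, dependency-free implementation whose full-covariance
components capture the parameter correlations that the partial-correlation
analysis later inspects.

Defaults (config-exposed, recorded in metadata): $K = 3$ components,
64 hidden units, learning rate $10^{-3}$, batch 256, up to 60 epochs with
patience 10, 10% validation split, `n_pca = 50`. For the recovery
experiments the configuration (`n_pca = 40`, 48 hidden units, $K = 3$)
was selected by validation loss against four larger alternatives.

`sample_posterior()` draws from the fitted mixture at the observed
features, maps draws into the parameter box (posterior-with-Jacobian on
the bounded scale), and attaches the stability mask; only stable draws
are retained, mirroring the design of training on the full prior and
filtering at sampling time. `posterior_predictive()` pushes retained
draws through the forward model on an individual connectome and
summarizes the reconstructed standardized PSD with its pointwise mean and
95% band. Three seed streams (prior/simulation, network training,
posterior sampling) are all recorded.

## Calibration and recovery diagnostics

`sbc_calibration()` implements simulation-based calibration: truths drawn
from the prior, observations simulated at the truth, and the rank of each
truth among its posterior draws recorded. Ranks use the *unfiltered*
draws and *unrestricted* prior truths, because that is the pairing for
which rank uniformity is exact in the well-trained limit; the chi-square
uniformity test (`sbc_uniformity()`) uses exact bin probabilities over the
$L + 1$ possible ranks. `recovery_experiment()` wires everything
together: one amortized posterior trained on a template, a cohort of
synthetic subjects, per-parameter 95% credible-interval coverage,
truth-versus-posterior-mean correlations, and SBC — written as JSON by
`write_recovery_report()`.

**Problem sizes.** The package's standard experiment is a 10-region
synthetic template, 40 frequencies, 5000 training simulations, 20
subjects, 1000 posterior draws, 200 SBC replicates of 100 draws — a
minutes-scale experiment that exercises every pipeline stage. Atlas scale
(68 regions, $10^5$ simulations) is the same code with larger arguments.

## The synthetic-data generator

`synth_connectome()` places regions uniformly in a 140 mm cube, takes
Euclidean fiber distances, and sets weights to
$e^{-d/40\,\mathrm{mm}}$ times symmetric lognormal noise (log-sd 0.5) —
reproducing the negative weight–distance association and heavy-tailed
edge weights of tractography connectomes. `make_synthetic_subject()`
draws a stable truth from the prior and emits noisy features per the data
model. What the generator does *not* emulate: streamline-count
quantization and consensus thresholding, subcortical/cortical asymmetries,
MEG sensor noise, source-leakage correlations, and the $1/f$ background of
real spectra. Passing tests therefore demonstrate the *inference
machinery* — calibration, coverage, contraction, reconstruction — under
the model's own generative assumptions, not performance on real MEG.

## The annealing baseline

`fit_annealing()` is the classical point-estimate comparator: a global
stochastic search for the parameters maximizing the Pearson correlation
between model features and the observation (the objective used here;
prior art defers its exact objective to earlier work, and a correlation
objective is scale-free against z-scored features). The search runs in
the unconstrained scaled-logit space — which makes box constraints
implicit — in three phases: a prior-shaped random scan (10% of the
budget) to seed the search, a simulated-annealing phase (50%), and a
Nelder–Mead polish (40%). Gain bounds are tried tier by tier, widest
first; the first tier whose optimum is stable wins. The default budget of
$10^4$ evaluations suits desk scale; the structure (annealing plus local
search) is the dual-phase scheme classical SGM fitting relies on.

## Evaluation statistics

* `psd_correlation()`: Pearson $r$ per region across frequencies, averaged
  over regions; zero-variance regions are excluded, not imputed.
* `spatial_correlation()`: the alpha-band spatial statistic
  $\hat a^\top W a / \sqrt{(\hat a^\top W \hat a)(a^\top W a)}$ with
  $W = (D + wI)$ symmetrized, $D$ the row-degree-normalized connectivity
  and $w = 10$ by default. The normalization (a weighted cosine) keeps the
  statistic in $[-1, 1]$ and hence comparable across subjects; the raw
  inner product is available via `normalize = FALSE`. $W$ is symmetrized
  because row normalization breaks symmetry.
* `partial_correlation_matrix()`: $-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$
  from the inverse covariance of posterior draws.
* `compare_methods()`: two-sided Welch $t$-test (chosen over the pooled
  test because per-subject score variances need not match across methods).

## Numerical choices

* dB convention: $20\log_{10}|X|$, equivalently $10\log_{10}|X|^2$; the
  floor $10^{-20}$ keeps exact zeros finite.
* Symmetry tolerance $10^{-8}$ relative on input matrices; larger
  asymmetries are averaged with a warning (directed streamline counts are
  conventionally averaged), and the fix is logged in the provenance
  attribute.
* All-zero rows survive row-degree normalization as zero rows: isolated
  regions are legal in synthetic graphs.
* Stability tolerance: pole real parts $< -10^{-9}$.
* MDN diagonal log-scales clamped to $[-7, 7]$; gradient norm clipped at
  50; divergent (non-finite) loss aborts with a diagnostic rather than
  continuing.
* Every stochastic entry point takes an integer seed and restores the
  caller's RNG state, so library use never clobbers a session's stream.

## Known limitations

* **Conduction speed is weakly identified at reduced scale.** Across its
  whole range, $v$ moves the 10-region feature vector by an order of
  magnitude less than the feature noise, so its posterior stays close to
  the prior and cross-subject recovery correlations for $v$ hover near
  zero. This is a property of the reduced-scale study conditions (few
  regions, z-scored features), not of the code path: the same pipeline
  recovers the time constants strongly (correlations near 0.8–0.9) and
  $v$'s credible intervals remain honest (coverage at nominal level).
  Atlas-scale connectomes with richer delay structure identify $v$
  better.
* Single-round (fully amortized) inference only; no sequential refinement
  toward one observation.
* The noise model is i.i.d. Gaussian on features; only its standard
  deviation is exposed. Structured (e.g. frequency-correlated) noise is
  out of scope.
* Matrix I/O is CSV; the mixture density network runs on CPU and is sized
  for $10^4$–$10^5$ training pairs, not GPU-scale corpora.
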