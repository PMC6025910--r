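---
title: "Chaos-kernel relevance vector machines for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-kernel relevance vector machines for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaosrvm)
```

## The problem

Motor-imagery brain-computer interfaces ask a subject to imagine one of a
few movements (left hand, right hand, feet, tongue) while multichannel EEG
is recorded, and then decode which movement was imagined from a single
trial. The discriminative signal is a *variance* change: imagining a
movement desynchronizes oscillations over the corresponding motor cortex
(ERD/ERS), so different classes concentrate band power in different
spatial directions. `chaosrvm` implements a complete four-class decoding
stack around one unusual ingredient — a kernel function derived from the
invariant density of a chaotic map — together with the machinery needed to
validate that derivation.

The stack is, bottom to top:

1. **Chaotic dynamics** (`iterate_logistic()`, `lyapunov_exponent()`,
   `arcsine_density()`, `transformed_density()`): the logistic map
   $Y_{n+1} = A\,Y_n(1 - Y_n)$, chaotic at $A = 4$ where its Lyapunov
   exponent is $\ln 2 > 0$ and its invariant density is the arcsine law
   $P(Y) = 1/(\pi\sqrt{Y(1-Y)})$.
2. **Kernels** (`kernel_spec()`, `chaos_kernel()`, `design_matrix()`):
   pushing the arcsine density through the logit transform
   $z = \ln(Y/(1-Y))$ gives the bell-shaped density
   $P(z) = 1/(\pi(e^{z/2} + e^{-z/2}))$ on the real line; replacing $z$
   by a scaled distance yields the chaos kernel
   $K(u, v) = \tfrac{1}{\pi}\left(e^{\beta\|u-v\|} + e^{-\beta\|u-v\|}\right)
   = \tfrac{2}{\pi}\cosh(\beta\|u-v\|)$.
   Gaussian and polynomial kernels are provided as baselines.
3. **RVM** (`rvm_fit()`): a sparse Bayesian binary classifier.
4. **CSP** (`fit_csp()`, `extract_features()`): two-class spatial
   filtering by simultaneous diagonalization of class covariances.
5. **One-versus-one pipeline** (`train_ovo()`, `cross_validate()`): six
   pairwise CSP+RVM units, majority voting, 3–24 Hz band-pass, repeated
   stratified cross-validation, Cohen's kappa.
6. **Synthetic data** (`generate_epochs()`): planted-pattern EEG-like
   epochs that make every layer testable without recordings.

## The chaos kernel and why it needs no Mercer condition

The chaos kernel *increases* with distance and is bounded below by
$2/\pi$, so it behaves very differently from a similarity kernel. It is
not positive semidefinite: for any two distinct points the $2\times 2$
Gram matrix has eigenvalues $\tfrac{2}{\pi}(1 \pm \cosh(\beta d))$, one of
which is negative for every $\beta, d > 0$. The test suite asserts this
counterexample rather than hiding it. Support vector machines require
Mercer kernels because their dual optimization assumes a PSD Gram matrix;
the RVM does not — its weights get independent Gaussian priors and the
penalized-likelihood Hessian $\Phi^\top B \Phi + A$ is made positive
definite by the prior's diagonal $A$ whenever the precisions are positive.
The fitter still guards the Cholesky factorization with escalating jitter
(starting at $10^{-8}$ times the mean diagonal, escalating tenfold at most
three times) because a non-Mercer design matrix can produce
near-singular curvature in the saturated regime.

Kernel parameter defaults ($\beta = 0.5$, Gaussian $\sigma = 0.95$,
polynomial $a = 1.26$, $d = 2$) are the operating points of the reference
protocol this package implements. The Gaussian exponent is
$\exp(-d^2/\sigma^2)$ — no factor of two — matching that protocol's
convention; `gaussian_half = TRUE` switches to the $2\sigma^2$ convention
for cross-checks against other software.

## The RVM training procedure

For training samples $u_i$ with labels $t_i \in \{0, 1\}$, the model is
$y(u; w) = \sum_i w_i K(u, u_i) + w_0$ squashed through the logistic
sigmoid, with prior $w_i \sim N(0, \alpha_i^{-1})$. Training alternates:

* **Laplace mode** (`laplace_mode()`): damped Newton maximization of
  $\log p(t \mid w) - \tfrac12 w^\top A w$. The Newton step solves
  $(\Phi^\top B\Phi + A)\,\Delta w = \Phi^\top(t - y) - Aw$ with
  $B = \mathrm{diag}(y_i(1-y_i))$, halving the step until the objective
  improves. At the mode the posterior is approximated as Gaussian with
  covariance $\Sigma = (\Phi^\top B\Phi + A)^{-1}$.
* **Precision re-estimation** (`update_alphas()`):
  $\alpha_i^{\text{new}} = (1 - \alpha_i \Sigma_{ii})/w_i^2$. The
  numerator $\gamma_i = 1 - \alpha_i\Sigma_{ii}$ measures how well the
  data determine weight $i$; as $\gamma_i \to 0$ the update sends
  $\alpha_i \to \infty$ and the basis function is pruned. Most precisions
  diverge, and the surviving kernel centers are the *relevance vectors*.

Numerical choices, each of which had to be fixed because the procedure is
only specified up to "appropriate convergence conditions":

* $\alpha_i$ initialized uniformly at $10^{-2}$ — a broad prior that
  starts near maximal flexibility (the common Tipping-style choice).
* Pruning at $\alpha > 10^9$; weights below $10^{-12}$ in magnitude and
  well-determinedness $\gamma$ below $10^{-10}$ are treated as prune
  signals directly, since both are the same $\gamma \to 0$ limit
  approached from different floating-point directions.
* Outer convergence when $\max_i |\Delta \log_{10}\alpha_i| < 10^{-3}$
  over retained weights, capped at 500 outer iterations; inner Newton
  stops at gradient $\infty$-norm $< 10^{-8}$ or 100 steps. The MacKay
  fixed point is known to approach pruning decisions slowly; the cap
  accepts a few not-yet-pruned basis functions rather than spending
  thousands of iterations resolving them. On clearly separable data the
  procedure converges and prunes long before the cap.
* The bias column is never pruned.
* Labels are encoded with the lexicographically smaller class as 0, so
  the six pairwise problems are deterministic.
* When *every* kernel basis is pruned the fitter errors by default —
  for a deliberately trained model this means the kernel cannot explain
  the data. Inside the pipeline (`rvm_control(on_empty = "bias_only")`)
  the same outcome instead yields a constant-probability model: on
  signal-free data, "predict the prior" is the correct answer and must
  not abort a cross-validation.

## CSP feature extraction

For a class pair, per-trial covariances are trace-normalized
($R = XX^\top/\mathrm{tr}(XX^\top)$, so every trial contributes equal
energy) and averaged per class. The filters solve the generalized
eigenproblem of $(R_a, R_a + R_b)$ by whitening the composite covariance;
the first $m$ rows maximize class-a variance ratio and the last $m$
class-b. Two implementation details:

* The last-$m$ filters are taken from the top eigenvectors of the
  *whitened class-b* covariance rather than the bottom eigenvectors of
  the whitened class-a one. In regular problems these coincide (the two
  whitened matrices sum to the identity), but when the inputs are rank
  deficient — e.g. noiseless rank-one covariances — the bottom of the
  class-a spectrum is a tie among null directions while the top of the
  class-b spectrum still identifies the discriminative one.
* An ill-conditioned composite (condition number $> 10^{12}$) receives a
  ridge of $10^{-10}\,\mathrm{tr}$; eigenvector signs are fixed so each
  filter's largest entry is positive, making output independent of the
  LAPACK backend's sign choices.

Features are normalized log variances
$f_k = \log( \mathrm{var}(Z_k) / \sum_i \mathrm{var}(Z_i))$ with
population variances (divide by $T$); $\sum_k e^{f_k} = 1$ by
construction. `m = 1` by default — the single most discriminative filter
per side, which is also what keeps six pairwise two-dimensional feature
spaces comparable.

## The pipeline and its evaluation

Preprocessing is a 4th-order Butterworth band-pass (3–24 Hz) applied
forward-backward for zero phase. Start-up transients are confined to
roughly one low-edge time constant ($f_s/f_{\text{low}} \approx 83$
samples at 250 Hz) at each epoch end; in-band gain is unity and 50 Hz
content is suppressed by more than 60 dB in the settled interior. Since
filtering is per-trial it is applied once, before fold splitting, with no
leakage risk.

Voting: the six units each cast one vote; ties are broken by summed
sigmoid probabilities over the tied classes' units, then by the smallest
label. The binary-to-multiclass aggregation rule is a genuine design
choice (nothing in the protocol fixes it); probability-sum tie-breaking
was chosen because it is deterministic and uses the probabilistic output
that distinguishes the RVM from margin classifiers.

Cross-validation is stratified per class with floor/remainder fold sizes
(72 trials over 5 folds gives 15, 15, 14, 14, 14), repeated with fresh
randomization, all RNG drawn from a caller-supplied seed without touching
the global RNG state. Reported: fold-level accuracies, their mean and
standard deviation, the pooled confusion matrix, Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$, and mean relevance-vector counts per
unit.

## What the synthetic generator does and does not emulate

`generate_epochs()` plants, for each trial of class $c$,
$\text{snr} \cdot p_c \, s(t)^\top + \text{noise}$: a Hann-enveloped
sinusoid $s(t)$ of unit RMS with per-trial random phase and carrier drawn
uniformly from 8–13 Hz (the mu band, inside the 3–24 Hz analysis band),
an orthonormal class pattern $p_c$ drawn once from the seed, and Gaussian
noise with channel covariance $\rho^{|i-j|}$, $\rho = 0.3$ (scalp
neighbors correlate; the Kac–Murdock–Szegő form is always positive
definite). Default geometry mirrors a standard four-class recording
(22 channels, 750 samples at 250 Hz, 72 trials/class); the test suite
uses a reduced preset (8 channels, 250 samples, 20 trials/class) chosen
so that fold-level training sets still dwarf the feature dimension.

This emulates exactly the structure CSP exploits — class-specific
oscillatory variance in fixed spatial directions — and nothing else. Real
EEG adds 1/f background spectra, artifacts, non-stationarity across a
session, and patterns that are neither orthogonal nor noise-independent.
Passing tests therefore demonstrate correctness of the algorithms, not
expected accuracy on real recordings: planted-pattern data at snr 10 is
*much* easier than a real subject. Real-data ingestion is out of scope by
design; anything that can produce an `epoch_set()` (trials × channels ×
samples plus labels and a sampling rate) plugs into the same pipeline.

Problem sizes used by the validation suite were chosen to characterize
each property at the smallest scale at which it is unambiguous: Lyapunov
estimates use $10^6$ iterates (the estimate is then within 0.01 of
$\ln 2$), invariant-density histograms $10^5$ iterates over 50 bins, and
pipeline checks the reduced generator preset with 5-fold
cross-validation repeated 5 times.

## Known limitations

* The chaos kernel's non-PSD Gram matrix means the same kernel cannot be
  transplanted into an SVM, and RVM training with it can need jitter in
  degenerate regimes.
* The MacKay update's slow pruning tail means relevance-vector counts
  reported under the default iteration cap are an upper bound; the
  decision function is unaffected in practice.
* The logit-density derivation motivates the kernel's *form*; it does not
  make the kernel a density, and $\beta$ remains a free parameter to be
  chosen (0.5 by default).
* `lyapunov_exponent()` floors $|1 - 2Y|$ at $10^{-300}$ before taking
  logs so a finite-precision hit on the critical point cannot produce
  $-\infty$; estimates at rates with superstable orbits are therefore
  large negative numbers rather than $-\infty$.
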