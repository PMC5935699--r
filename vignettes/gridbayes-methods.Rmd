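---
title: "Lattice-based inference of time-varying parameters: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-based inference of time-varying parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridbayes)
```

## The two-level model

`gridbayes` treats a time series $d_1, \dots, d_N$ as generated by a
*low-level* observation model with parameters $\boldsymbol\theta_t$
that themselves evolve according to a *high-level* model with
hyper-parameters $\boldsymbol\eta$. The low-level likelihood must
factorize over time steps — each $L_t^{(i)} = p(d_t \mid
\theta^{(i)}, d_{t-1})$ may depend on the current parameters and past
*data*, but not on past *parameter* values. This admits independent
observations (Poisson counts, Gaussian means, von Mises angles,
Rayleigh speeds) and autoregressive data models (the scaled AR-1
return process), but excludes moving-average models and long-range
correlated likelihoods.

Discretizing $\boldsymbol\theta$ on a regular lattice of cell centers
with voxel size $\Delta_\theta$ turns the filtering recursion into
elementwise products and small linear maps:

$$\alpha_{t+1}^{(i)} = L_{t+1}^{(i)} \cdot T_{t+1}\!\left(\alpha_t\right)^{(i)},
\qquad
p(\{d\}\mid\boldsymbol\eta) = \sum_i \alpha_N^{(i)} \Delta_\theta .$$

The transformation $T$ is *norm-preserving*: it redistributes
posterior mass without changing its total, so the running sum of the
per-step normalization constants is exactly the model evidence. That
single number is what enables everything else in the package:
hyper-parameter grids are scored by their evidences, combined into a
compound evidence $\sum_j p(\{d\}\mid\eta_j)\,p(\eta_j)$, normalized
into hyper-posteriors, and used as weights for model-averaged
parameter estimates; two competing high-level models can be compared
per data point in an online stream.

Smoothed (all-data) posteriors come from the backward recursion
$\beta_t = T'_{t+1}(L_{t+1}\cdot\beta_{t+1})$ and
$p(\theta_t \mid \{d\}) \propto \alpha_t \beta_t$.

## Numerical choices

**Lattices are cell midpoints.** `param_grid(lower, upper, n)` places
centers at `lower + (i + 1/2)(upper - lower)/n`. The stated open
intervals (e.g. a rate in $]0, 6[$) are therefore respected without
ever evaluating a density at a singular endpoint ($1/\sqrt\lambda$,
$1/s$). The alternative endpoint-inclusive convention would change
results at $O(\Delta_\theta)$; nothing downstream depends on which is
chosen, but the midpoint form is used consistently, including by the
synthetic generators.

**Improper priors are normalized on the truncated support.** Evidence
values are only meaningful with proper priors; the lattice bounds
define the support, and Jeffreys weights are renormalized there. As a
consequence evidence values are comparable across lattice resolutions
but only at *identical* support.

**The Gaussian random walk is a column-stochastic kernel.** Kernel
weights are CDF differences across cell boundaries (accurate also for
kernel widths below one cell), and each *source* cell's column is
renormalized to one, which retains the mass that would diffuse past
the lattice edge. Two properties follow exactly, not approximately:
every input's norm is preserved, and the transformation is linear —
i.e. the forward pass is literally summation over the paths of a
Markov chain, which is what the brute-force enumeration oracle in the
test suite checks to $10^{-10}$. The convolution itself runs via
direct filtering for small problems and FFT for large ones; the two
branches agree to machine precision and tiny FFT negatives are
clamped.

**Abrupt jumps are an additive mixture.** The minimal-probability
transformation is implemented as
$T(w) = (1 - p_\mathrm{min})\,w + p_\mathrm{min}\,\mathrm{flat}\cdot\|w\|$:
the addition of a small constant followed by a norm-preserving
rescaling. Every cell is guaranteed at least $p_\mathrm{min}$ times
the flat density, the map is linear (so the same path oracle applies),
and $p_\mathrm{min} = 1$ degenerates to a flat reset. An elementwise
floor followed by rescaling would behave almost identically but is
nonlinear and can leave cells below the nominal floor after rescaling.

**Backward operators are exact adjoints.** For the smoothed posterior
of the discretized chain to be exact, $T'$ must be the adjoint of the
forward kernel. For the Gaussian kernel and the jump mixture the
adjoint equals the forward map in the lattice interior (self-adjoint);
for the deterministic shift it is the pullback, which equals a shift
by $-\delta$ away from the edges. The distinction only matters within
a kernel width of the boundary.

**Deterministic trends are incremental shifts.** A trend
$\mu_t = f(t)$ is realized as per-step displacements
$\delta_t = f(t+1) - f(t)$ with linear sub-cell interpolation and edge
accumulation, so the mean path is continuous at a change-point (a
literal reading of "$\mu_t = a\,t$ after $t_1$" would jump there,
which we take to be unintended). Fractional shifts necessarily diffuse
a small amount of mass — variance at most $f(1-f)\Delta_\theta^2$ per
step — so a forward-then-backward shift round-trips exactly only for
integer-cell displacements; at the case-study resolutions this
diffusion is far below the observation noise.

**Degenerate inputs.** A posterior that vanishes entirely (a data
point impossible under the model) is a hard error in `gb_fit()` — it
signals model/data incompatibility rather than being silently
re-flattened. The one exception is hyper-grid scans inside
`climate_study()`: a trend combination that races off the lattice
makes the remaining data impossible *for that hyper-combination only*
and is assigned log-evidence $-\infty$, i.e. zero posterior weight.

**Missing data and prediction.** Missing points (`NA`) contribute a
flat improper likelihood factor $L \equiv 1$; the step then applies
only the transformation and adds exactly zero to the log evidence.
Prediction appends empty slots and reads off the propagated
distributions; with no data beyond the horizon, smoothing and
filtering coincide there.

**Scale engineering in the pipelines.** Two exact factorizations keep
the published hyper-grids tractable: (i) a change-point reset erases
all memory, so the disaster-rate evidence factorizes into prefix and
suffix segment evidences — one forward and one adjoint sweep per drift
magnitude replace one run per (change-point, drift, drift)
combination; (ii) the temperature scenarios share their constant-mean
prefix across candidate onsets, and identity dynamics after a plateau
onset reduce the suffix to a cumulative likelihood product. Both
shortcuts are verified against monolithic engine runs in the tests.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| lattice size `n` | resolution of $\theta$ | per case study (e.g. 1000 rates on $]0,6[$ yr$^{-1}$, $100\times400$ for (correlation, volatility)) | published analysis settings |
| `sigma` (random walk) | drift per step, parameter units | hyper-grid, e.g. $[0,1]$ (rate), $[0,5]$ ($\kappa$), $[0,0.2]$ µm min$^{-1}$ ($s$) | wide enough to span "constant" to "fast" dynamics |
| `p_min` | relative jump floor | $\{0, 10^{-6}, 10^{-3}\}$ | spans no-jump to frequent-jump regimes |
| online model priors | per-step prior of the memoryless model | $1/390$ | one expected anomaly per 390-minute trading day |
| anomaly threshold | flagging level on $p(\mathrm{chaotic})$ | 5 % | published operating point |
| climate horizon | empty prediction slots | 25 yr | reaches 2026 from data ending 2001 |

## What the synthetic generators emulate — and what they do not

Each generator inverts its case study's observation model under known
parameter paths and a mandatory seed: Poisson counts with change-points
and reflected-Gaussian rate drift; persistent 2-D walks whose relative
turning angles are von Mises draws (Best–Fisher sampler) and whose
speeds are Rayleigh; AR-1 returns via the exact recursion with optional
injected parameter jumps; temperature series with piecewise
(continuous) trends and known per-year noise. Reflection (rather than
truncation) at the lattice bounds keeps drifting paths' increments
symmetric.

They deliberately do *not* emulate: measurement artifacts in cell
tracking (segmentation noise, collisions), market microstructure
(volume, discrete ticks, scheduled announcements), or long-range
correlated climate noise. A green recovery test therefore establishes
that the inference machinery identifies the parameters of its own
generating model at realistic noise — not that the low-level models
are adequate for any particular real dataset.

Generator defaults follow the case studies they emulate. Where a test
needed a sharper statement than realistic noise supports, the
construction is documented at the test site: the online-selection
check injects a one-minute 30× volatility spike (a "flash event"),
because a persistent jump leaves secondary flags while the gradual
model re-adapts and a moderate one-minute jump is unobservable
whenever the driving noise draw happens to be small; and the
temperature recovery asserts the onset year to ±5 yr at a
reconstruction noise of 0.06 °C — the information content of a
0.01 °C yr$^{-1}$ ramp simply does not localize the onset more tightly
(the published real-data uncertainty is ±6 yr).

## Design decisions that were genuinely open

- **AR-1 first step.** The initial condition is unstated in the usual
  formulation; we condition on $r_0 = 0$. The factor is common to all
  compared models, so evidence *ratios* are unaffected.
- **Turning-angle convention.** The velocity-increment orientation
  (`"increment"`, the literal transcription of the atan2 definition)
  and the conventional signed relative angle (`"relative"`) are both
  implemented; `"relative"` is the default and what the trajectory
  generator inverts, because a zero-centered von Mises model of
  *persistence* presumes angles measured relative to the previous
  heading. Outputs carry the convention as an attribute.
- **Online state propagation.** Each competing high-level model
  advances its own forward states independently; the memoryless model
  is evaluated one step ahead from a flat prior each minute, and the
  fixed per-step model priors (389/390 vs 1/390) are re-applied rather
  than propagated.
- **Volatility-marginal fit.** The compound-gamma mixture integral has
  a closed form (a scaled beta-prime density), so the fit maximizes
  that exact likelihood on the pooled lattice instead of quadrature;
  a test cross-checks the closed form against adaptive quadrature.
- **Pooled market distribution.** Per-minute hyper-averaged smoothed
  posteriors are summed with equal weight per minute across days.
- **Retention filters.** "Tracked ≥ 2 h" is read as ≥ 25 consecutive
  5-minute frames (gaps split tracks); "migrated ≥ 30 µm away" as
  $\max_t |r_t - r_0| \ge 30$ µm. The temperature uncertainty column
  is a *two*-standard-error interval, so $\sigma_t$ is half of it.

## Known limitations

- At most ~3 low-level parameter dimensions are practical: cost and
  memory grow with lattice size × series length.
- Evidence values depend on the lattice support; comparisons are only
  valid across models sharing it.
- Non-regular/adaptive lattices and state-dependent transition kernels
  are out of scope.
- The climate low-level model ignores long-range temporal correlation
  of reconstruction errors, so predictive uncertainties are likely
  understated.
- The verification of the published temperature numbers requires the
  third-party regional reconstruction file, which is not
  redistributable; without it that check reports red by design, while
  the synthetic scenario tests remain green.
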