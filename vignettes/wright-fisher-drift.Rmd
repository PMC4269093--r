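---
title: "A global spectral solution for random genetic drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A global spectral solution for random genetic drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfdrift)
```

## The model

The two-allele Wright–Fisher model describes pure random genetic drift at a
single diploid locus: a population of fixed size $N$ carries $2N$ gene
copies, and the count $Y_n$ of allele $A_1$ in generation $n+1$ is a binomial
resample of the frequency in generation $n$,

$$P(Y_{n+1} = j \mid Y_n = i) = \binom{2N}{j}
  \left(\tfrac{i}{2N}\right)^j \left(1 - \tfrac{i}{2N}\right)^{2N-j}.$$

The states $0$ and $2N$ are absorbing: once an allele is lost it never
returns, and absorption happens almost surely. Rescaling time and frequency,
$t = n/2N$ and $X_t = Y_t/2N$, and letting $N \to \infty$ gives the drift
diffusion on $[0,1]$, whose density solves the Kolmogorov forward
(Fokker–Planck) equation

$$u_t = L u = \tfrac12 \,\partial_x^2\big(x(1-x)\,u\big), \qquad
  u(x, 0) = \delta_p(x).$$

The classical spectral treatment of this equation expands $u$ in the
eigenfunctions of $L$ — here a Gegenbauer family ($\alpha = 3/2$,
normalised so $Y_0 = 1$, $Y_1 = 3z$, transplanted to $[0,1]$ by
$X_m(x) = Y_m(1-2x)$, with eigenvalues $-\lambda_m = -(m+1)(m+2)/2$) — but
the interior series alone loses mass: probability flows irreversibly into
the boundaries. The object this package implements is the *global* solution,
which adds explicit Dirac atoms at $0$ and $1$:

$$u(x,t) = \sum_{m \ge 0} c_m X_m(x) e^{-\lambda_m t}
 + \Big\{1 - p + \sum_m c_m a_{m,0} e^{-\lambda_m t}\Big\}\,\delta_0
 + \Big\{p + \sum_m c_m a_{m,1} e^{-\lambda_m t}\Big\}\,\delta_1,$$

with universal boundary coefficients $a_{m,0} = -\tfrac12$,
$a_{m,1} = (-1)^{m+1}\tfrac12$ and spectral weights
$c_m = w(p) X_m(p) / (X_m, wX_m) = 8\,w(p)X_m(p)(m + 3/2)/((m+1)(m+2))$,
$w(x) = x(1-x)$. This measure-valued solution conserves mass and the mean
frequency exactly, satisfies the weak (adjoint-paired) formulation
$(u_t, \phi) = (u, L^*\phi)$ for smooth test functions, and deforms
$\delta_p$ continuously into $p\,\delta_1 + (1-p)\,\delta_0$. Every quantity
of interest reads off it directly:

* loss / fixation probabilities — the atom masses;
* coexistence probability $\sum_m c_{2m} e^{-\lambda_{2m}t}$ (odd terms
  integrate to zero);
* mean absorption time
  $E(T) = \sum_m c_{2m}/\lambda_{2m} = -2\{p\ln p + (1-p)\ln(1-p)\}$, and the
  second moment $\sum_m 2c_{2m}/\lambda_{2m}^2$;
* frequency moments $m_n(t) = (u, x^n)$, via exact integrals of monomials
  against the basis;
* heterozygosity $H_t = (u, 2w) = 2p(1-p)e^{-t}$ — a single spectral mode, so
  no truncation error at all.

```{r}
sc <- spectral_coefficients(p = 0.4, M = 100)
d <- drift_density(sc, t = 1, xs = seq(0.05, 0.95, by = 0.05))
c(atom0 = d$atom0, atom1 = d$atom1,
  mass = pair_density(sc, d, function(x) rep(1, length(x)), 0L))
absorption_summary(0.5)
```

## Parameters that matter

* `p` — initial frequency of $A_1$, dimensionless in $[0,1]$. At `p` of 0 or
  1 every $c_m$ vanishes and the solution is the constant boundary atom; the
  code short-circuits these cases.
* `t` — diffusion time in units of $2N$ generations ($t = 1$ is $2N$
  generations). The absorption probabilities do most of their rising on
  $t \in (0, 5)$.
* `M` — truncation order of the interior series. Because
  $\lambda_m \sim m^2/2$, convergence is extremely fast for moderate $t$:
  the defaults ($M = 100$ for densities and probabilities, $M = 200$ for the
  absorption-time series, where the terms decay only algebraically through
  $1/\lambda_{2m}$) give residuals below $10^{-8}$ and $10^{-6}$
  respectively on $p \in [0.05, 0.95]$. Near $t = 0$ the series approximates
  a delta function and converges slowly; the code computes anyway and emits
  a truncation warning when the first-omitted-term bound
  $|c_{M+1}|\max|X_{M+1}|e^{-\lambda_{M+1}t}$ exceeds $10^{-10}$ or
  $t < 0.01$.
* `N`, `i0` — the discrete chain's population size and initial count;
  `seed` — mandatory for Monte-Carlo ensembles (single Mersenne-Twister
  stream, bit-reproducible).

## Numerical choices

**Quadrature.** All polynomial integrals (weighted norms, boundary
coefficients, weak pairings) use Gauss–Legendre rules sized from the
integrand degree (node count $\lceil(\deg+2)/2\rceil + 1$), so they are
exact up to rounding; no symbolic algebra is involved. The closed forms
$(X_m, wX_m) = (m+1)(m+2)/(8(m+3/2))$, $a_{m,0} = -1/2$,
$a_{m,1} = (-1)^{m+1}/2$ serve as cross-checks in the tests, not as the
implementation of the integrals.

**Basis evaluation.** $Y_m$ is evaluated by the forward three-term
recurrence, stable on the orthogonality interval at the degrees used here; a
configurable cap (`options(wfdrift.max_degree = )`, default 500) triggers a
warning rather than an error beyond the tested range. Series evaluations
share one pass of the recurrence across all degrees. A monomial-coefficient
representation (computed once per degree and cached) backs the exact
operator algebra $L$, $L^*$; it is well-conditioned for coefficient-wise
identities at any tested degree but, like any monomial basis, loses accuracy
for *point evaluation* above degree $\approx 20$ — point evaluation always
goes through the recurrence.

**Atoms are scalars.** Dirac masses are never represented as grid spikes;
the weak pairing adds $\mathrm{atom}_0\,\phi(0) + \mathrm{atom}_1\,\phi(1)$,
which is exactly the weak formulation's reading of the measure. Small
negative interior values at low `M` and small `t` are a Gibbs artifact of
truncation and are returned as computed; `clamp = TRUE` zeroes them for
plotting only, preserving the mathematical object in the API.

**Mollified plots.** For figures the atoms can be replaced by boundary
half-Gaussians $(k/\sqrt{2\pi})e^{-x^2k^2/2}$ (and mirrored at 1). Each
bump integrates to about $1/2$ over $[0,1]$, so the plotted bump area is
half the atom mass; the classical mollifier is kept verbatim for
comparability rather than rescaled.

**Absorption-time series.** Summed in ascending order with Kahan
compensation (terms alternate in sign through $X_{2m}(p)$). The agreement
with the entropy closed form is verified to $10^{-6}$ absolute at $M = 200$,
and the second moment against the independent survival-function identity
$E(T^2) = \int_0^\infty 2t\,P(T > t)\,dt$ integrated adaptively.

**Moment series.** The $n$-th moment is implemented through the exact
integrals $\int x^n X_{i-1}$ (closed product form, accumulated
factor-by-factor) plus the $a_{i-1,1}$ atom terms, rather than the compact
printed product alone; the two agree because
$\int x^n X_{i-1} + a_{i-1,1} = (-1)^i \tfrac12\prod_{k=1}^i
\frac{n-k}{n+k}$, which vanishes for $i > n$ in one factor yet keeps the
tail terms that the atom contributes — the tests verify the series against
density-based pairings with atoms to $10^{-7}$.

**Moment ODE.** The diffusion-limit moment system
$\dot m_k = \tfrac{k(k-1)}{2}(m_{k-1} - m_k)$ is lower-triangular and
non-stiff at the orders used; it is integrated with `deSolve::ode` at
`rtol = atol = 1e-12` and cross-checked against the closed $k = 2$ solution
and the spectral series.

**Discrete chain.** The binomial kernel uses `stats::dbinom` (log-scale
internally), exact propagation uses dense matrix–vector products up to
$10^4$ states and on-the-fly row generation with far-tail truncation above
that. The per-generation moment recursion is offered in two readings: the
drift approximation $m_k \mapsto \{1 - k(k-1)/(4N)\}m_k + \{k(k-1)/(4N)\}
m_{k-1}$ (one generation is $\delta t = 1/2N$ of diffusion time), and the
exact binomial update via Stirling numbers of the second kind, which is the
reference — the approximation is its truncation at order $1/N$.

## What the tests show — and what they do not

The package has no external data; its "synthetic data" is the discrete chain
itself, which is the exact finite-$N$ object the diffusion approximates. The
consistency suite checks, at desk scale chosen to keep the full run under a
minute: chain heterozygosity after $\lfloor 2Nt \rfloor$ generations within
2% of $2p(1-p)e^{-t}$ at $N = 100$; exact mean absorption generations within
2% of $-4N\{p\ln p + (1-p)\ln(1-p)\}$ at $N = 200$; and a seeded
$10^4$-path ensemble recovering the fixation fraction $p$ within
$3\,\mathrm{SE}$. These confirm the diffusion limit at moderate $N$ and the
correctness of both implementations against each other; they say nothing
about biology beyond the model's own assumptions — no mutation, selection,
migration, or variable population size, non-overlapping generations, a
single biallelic locus.

## Design notes

* The module surfaces are plain functions with light S3 classes
  (`spectral_coefficients`, `mixed_density`, `quantity_series`, `wf_chain`,
  `wf_ensemble`) — the natural shape for a numerical/population-genetics
  library whose data are parameter sets and series, not sequence or range
  containers.
* The CLI (`exec/wf-drift`) is a thin `optparse` wrapper over the exported
  `run_density()`, `run_quantities()`, `run_simulate()`, `run_validate()`
  functions, which are the tested surface.
* `run_validate()` re-measures every structural identity (orthogonality,
  eigen-identities, conservation laws, partition of unity, monotonicity,
  closed-form agreement, chain martingale) and prints residuals; truncation
  warnings raised along the way are collected into the report rather than
  silenced or turned into failures.
* $0\ln 0 := 0$ in the entropy closed form; degenerate starts
  $p \in \{0, 1\}$ short-circuit every quantity to its absorbed value.

## Limitations

Only the $\alpha = 3/2$ Gegenbauer family (the two-allele drift operator) is
implemented, in double precision; the practical degree cap is 500. The
multi-allele simplex generalisation, mutation/selection variants, and
grid-based PDE solvers are out of scope. At $t \lesssim 10^{-2}$ the interior
series needs $M$ in the hundreds and the evaluation, while computed, carries
a truncation warning — for the discrete picture at such short horizons, use
the exact chain instead.
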