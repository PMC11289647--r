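---
title: "Lateralization as energy and free-energy minimization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralization as energy and free-energy minimization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latmin)
```

# The scientific problem

Left–right asymmetry of brain and behaviour occurs at two distinct levels.
An individual animal can be lateralized (one hemisphere dominating a
function), and a population can be lateralized (a majority sharing the same
direction of bias, with a persistent minority of the opposite bias — human
left-handers being the canonical example). `latmin` implements a physical
account of both levels in which asymmetry is not an accident of development
or a purely game-theoretic outcome but the configuration that minimizes an
energy (individual level) or a free energy (population level).

# Individual level: two coupled doublets

Each functional unit (say, a hemisphere) is a two-state system, a doublet
$\psi = (\psi_R, \psi_L)$ acted on by the spin-1/2 generators
$\tau_i = \sigma_i/2$. Two units couple through the only
rotation-invariant scalar available, $g\,\bar\tau_1\cdot\bar\tau_2$ with a
constant $g$. The four product states resolve into three symmetric triplet
states ($s_{tot}=1$) and one antisymmetric singlet ($s_{tot}=0$), on which
the scalar coupling takes the values $+1/4$ and $-3/4$ respectively. With
$g > 0$ the singlet — the configuration that changes sign under the
R$\leftrightarrow$L exchange — is therefore the unique ground state, with a
singlet–triplet gap of exactly $g$ (1 in dimensionless units at the default
$g = 1$):

```{r}
energy_spectrum(g = 1)
attr(energy_spectrum(g = 1), "gap")
```

Conventions fixed here (they matter for reproducibility, not for the
physics): basis order (RR, RL, LR, LL); R is the $\tau_3$ eigenvector with
eigenvalue $+1/2$ (forced by attaching $s_{3,tot} = +1$ to the RR state);
ladder operators $\tau_\pm = \tau_1 \pm i\tau_2$, so $\tau_+$ maps L to R;
the global phase of returned states makes the first nonzero amplitude
real-positive; $g > 0$ so that the singlet is the minimum.

A numerical note: the mixed pair states carry $1/\sqrt 2$ amplitudes, and
evaluating the quadratic form on pre-normalized amplitudes loses one or two
ulp. The coupled-pair objects therefore retain their exact integer
amplitudes, and `scalar_coupling_expectation()` divides the (exactly
representable, dyadic) quadratic form by the integer squared norm, making
the $-3/4$, $+1/4$ and gap values exact in double precision.

# Population level

## Collective states and the order parameter

A population of $N$ units, each definitely R or L, with counts
$N_R = \ell$ and $N_L = N - \ell$, is represented by the symmetric (Dicke)
state $|\ell\rangle$. The package works in the $(N+1)$-dimensional
symmetric sector rather than the $2^N$ product space; the two agree exactly
(the test suite checks every matrix element against a brute-force
symmetrization oracle up to $N = 10$), and the sector representation stays
exact for $N$ in the thousands. The asymmetry order parameter is

$$M = \langle \ell | S_3 | \ell \rangle = \ell - N/2 = (N_R - N_L)/2,$$

a collective property: $M \ne 0$ signals population-level asymmetry under
the R/L exchange.

## The hyperbolic-angle parameterization

Writing $N_L/N = a$ and $N_R/N = 1 - a$, the decomposition $a + (1-a) = 1$
is parameterized in full generality by $a = \tanh^2\theta$,
$1 - a = 1/\cosh^2\theta$, so the ratio is
$X = N_L/N_R = \sinh^2\theta$. Only $\theta \ge 0$ is used
($\theta \to -\theta$ changes no observable). The probability of drawing
one R together with $X$ L's is the geometric law

$$W_X = \frac{\tanh^{2X}\theta}{\cosh^2\theta}, \qquad \sum_{X \ge 0} W_X = 1 .$$

The symbol $X$ plays a dual role in this formalism: a nonnegative integer
index in $W_X$ (where the normalization is a geometric series) and the
continuous ratio $X(\theta) = \sinh^2\theta$. `latmin` keeps the two
readings explicitly separate — `occupation_probability()` accepts only
integer indices, `ratio_from_theta()` returns the continuous ratio — and
reconciles them only through $\theta$.

## Entropy, free energy, Boltzmann equilibrium

The entropy of the population configuration is

$$S(\theta) = -( \sinh^2\theta \ln \sinh^2\theta - \cosh^2\theta \ln \cosh^2\theta ),$$

equivalently $(1+X)\ln(1+X) - X\ln X$, which is also exactly the Shannon
entropy $-\sum_X W_X \ln W_X$ of the geometric law (the identity
$E[X] = \sinh^2\theta$ makes the two coincide; the package computes both
routes and the tests assert their equality rather than assuming it). The
$\theta = 0$ limit is handled analytically ($x \ln x \to 0$), never by
epsilon-shifting. With configuration energy $H_X = X E_X$ ($E_X$ a constant
energy scale; any $X$-dependence of $E_X$ would change the stationarity
condition and is deliberately not modelled) and inverse temperature $\beta$
($k_B = 1$, all quantities dimensionless), the free energy is

$$F(\theta) = X E_X - S(\theta)/\beta .$$

Stationarity $dF/d\theta = 0$ at $\theta > 0$ gives
$-\beta E_X = \ln\tanh^2\theta = \ln (N_L/N)$: the equilibrium fraction of
L-individuals is the Boltzmann factor $N_L/N = e^{-\beta E_X}$, and

$$X^* = \frac{e^{-\beta E_X}}{1 - e^{-\beta E_X}}, \qquad
  \theta^* = \mathrm{artanh}\, e^{-\beta E_X/2} .$$

Both boundaries are excluded on physical grounds: $N_L/N = 1$ needs
$\beta E_X \to 0$ (infinite temperature), $N_L/N = 0$ needs
$\beta E_X \to \infty$ (zero temperature), so the equilibrium ratio is
always nonzero and finite — a population is never exactly all-L or all-R.
The balanced population $X = 1$ corresponds to $\beta E_X = \ln 2$:

```{r}
stationarity_solve(beta = 1, E_X = log(2))
```

The curvature at the stationary point has the closed form
$d^2F/d\theta^2|_{\theta^*} = 4/\beta > 0$ — always a minimum. Because
$\beta$ and $E_X$ enter equilibrium quantities only through $\beta E_X$,
the API exposes both (for readability of the temperature interpretation)
but documents the degeneracy; `temperature_from_ratio()` inverts the
relation to define $T$ from an observed ratio. Numerically,
`stationarity_solve()` uses the closed form; an independent root of
$dF/d\theta$ on the monotone substitution $u = \tanh^2\theta \in (0,1)$
(via `uniroot`, tolerance $10^{-14}$) is kept internally purely for
cross-validation.

## The su(2) → e(2) contraction at large N

The collective ladder operators obey $[S_+, S_-] = 2S_3$ at every $N$.
Rescaled by $1/\sqrt N$ at fixed asymmetry $M$, the commutator
$[S_+/\sqrt N, S_-/\sqrt N] = 2S_3/N$ approaches the scalar $2M/N \to 0$
on any fixed window of Dicke states around $\ell$: the ladder operators
become commuting "translations" $N_R \to N_R \pm 1$, $N_L \to N_L \mp 1$,
while $S_3$ (the rotation generator) is untouched — the spherical su(2)
structure contracts to the cylindrical e(2) one, with the parameter count
(three) preserved. `contraction_residual()` measures the operator norm of
$[S_+/\sqrt N, S_-/\sqrt N] - (2M/N) I$ on a window of 11 Dicke states
(configurable; 11 keeps the diagnostic local to the population's actual
composition while remaining well inside the basis for every tested $N$).
The residual decays as $O(1/N)$, which the tests confirm over
$N \in \{20, 40, 80, 160\}$ by a log–log slope within $-1 \pm 0.2$.
Physically: a large population is felt by one individual as a single
collective agent, and the environment coupling
$\lambda(b^\dagger S_- + b S_+)$ is amplified to the strong-coupling scale
$\lambda N$ (peak matrix elements of $S_\pm$ near the equatorial states
grow linearly in $N$). The environment mode $b$ is treated as a classical
complex amplitude: no mode dynamics are modelled, only the coupling
structure and its $N$-scaling.

# Relaxation dynamics

The equilibrium theory does not prescribe an equation of motion, so the
package provides two and states their rationale:

* **Metropolis flips** ($N_L \to N_L \pm 1$, acceptance
  $\min(1, e^{-\beta \Delta F_N})$, with $F_N$ the free energy at
  $\theta(N_L/N)$) are chosen because their stationary law is *exactly* the
  Boltzmann structure the equilibrium analysis derives,
  $\pi(N_L) \propto e^{-\beta F_N(N_L)}$ — so the claim that a perturbed
  ratio $X'$ relaxes back to equilibrium becomes a testable property
  (detailed balance is verified by direct matrix computation at $N = 10$,
  and the sampled histogram against exact enumeration at $N = 50$).
  Boundary states $N_L \in \{0, N\}$ are excluded (infinite-$F$
  convention), mirroring the exclusion of all-L/all-R populations; a
  boundary start is nudged inward with a warning.
* **Gradient flow** $d\theta/dt = -\eta\, dF/d\theta$ (explicit Euler) is
  the deterministic counterpart; since the curvature at the minimum is
  $4/\beta$, any step $\eta < \beta/2$ converges, and the endpoint matches
  the closed-form $\theta^*$ to $10^{-8}$ in the tests.

Because $F$ is intensive (it depends on $N_L$ only through the ratio), the
Boltzmann law over $N_L$ is *broad*: at $N = 1000$ and
$\beta E_X = \ln 2$ the stationary standard deviation of $N_L$ is about
219 and the stationary mean of $X$ is about 1.09 rather than exactly
$X^* = 1$ (the mean of a ratio is not the ratio at the mode). Tests of
start-independence therefore compare time-averaged ratios from opposite
starts against each other and against the exactly enumerated stationary
expectation, with Monte-Carlo errors from batch means (30 batches), rather
than against $X^*$ itself. Problem sizes used by the test suite — $N = 50$
with $1.5\times10^6$ samples for the histogram, $N = 200$ with
$1.5\times10^5$ steps, three seeds and starts $\{20, 180\}$ for
start-independence — were chosen so that the random-walk autocorrelation
(of order $\mathrm{sd}(N_L)^2$ steps) leaves enough effective samples for
the batch-means error to be meaningful.

Perturbations are modelled as instantaneous displacements of $N_L$ (the
starting value); no richer perturbation process is specified by the
theory, and none is invented.

## Evolutionary fitness layer

The game-theoretic account of population lateralization uses a fitness
$f(X) = a(X) + c\,s(X)$, with $a$ an antagonistic (competition) and $s$ a
synergistic (cooperation) component and $c$ their relative weight;
`ess_equilibrium()` maximizes it by coarse grid plus local refinement. The
functional forms of $a$ and $s$ are *not* shipped as scientific claims —
the theory here does not fix them — so they are user-supplied; the toy
quadratics in the tests and the CLI exist only to exercise the machinery
(e.g. for $a = -(X-1)^2$, $s = -(X-3)^2$ the equilibrium is
$X^*(c) = (1+3c)/(1+c)$, increasing in $c$, which the tests reproduce).
A fitness flat over a spread-out set of near-maximal ratios is reported as
degenerate rather than returning an arbitrary maximizer.

# What the simulations do and do not show

The package contains no empirical data; every input is a model parameter
(the synthetic conditions are the model itself). Passing tests show that
the implementation reproduces the theory's closed forms and structural
properties exactly or to stated tolerance. They do not show that real
populations follow Metropolis dynamics on this free energy, that $E_X$ is
constant in $X$, or that the classical treatment of the environment mode
is adequate — those are modelling assumptions, flagged above. Finite-size
corrections beyond the exact finite-$N$ enumeration, quantized environment
dynamics, spatial or network population structure, and
mutation/inheritance genetics are out of scope.

# Numerical choices, in one place

* Tolerances: $10^{-12}$ for normalization/Hermiticity of the small exact
  matrices; $10^{-14}$ for the cross-validating root solve; $10^{-10}$ for
  geometric-sum truncation checks.
* Degenerate inputs: $\theta = 0$ via analytic limits; $\ell = 0$ leaves
  $X$ undefined and flagged (`X_defined = FALSE`), never silently
  infinite; boundary fractions $N_L \in \{0, N\}$ are rejected where a
  $\theta$ is required.
* Counts are exact integers at the population layer; no real-valued
  $N_L$ is accepted there.
* RNG: one integer seed per stochastic run, recorded on the result object;
  the sampler saves and restores the caller's RNG state.
* CSV outputs carry 17 significant digits so re-reading reproduces the
  doubles bit-for-bit; JSON scalars are written unrounded.
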