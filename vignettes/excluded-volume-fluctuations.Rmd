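---
title: "Finite-volume density fluctuations with excluded volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-volume density fluctuations with excluded volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanofluct)
```

## The problem

The isothermal compressibility of a fluid is tied to its density
fluctuations: in an open volume $V$ in contact with a reservoir,

$$\nu \;=\; \frac{\langle \delta N^2\rangle}{\langle N\rangle}
   \;\xrightarrow{\;V\to\infty\;}\; \rho\,\kappa_T/\beta .$$

At the nanometre scale this identity breaks down in a specific way: the
particle number $N$ counted from particle *centres* is a discrete
variable, while $\kappa_T$ is continuous.  Counting point-like centres
in a subvolume whose size is comparable to the particle diameter
$\sigma$ produces a large, systematic $1/L$ size dependence of $\nu(L)$
— often misread as a physical "surface term" in the compressibility —
even in systems whose compressibility is rigorously size-independent.

`nanofluct` implements the correction: particles are given a finite,
uniform density profile of diameter $a$, so the window content becomes
a continuous variable.  At the level of pair correlations this amounts
to replacing the radial distribution function $g(r)$ by a **modified
RDF** $\tilde g(r)$, the convolution of the full two-particle density —
pair part $\rho^2 g$ *plus* the diagonal self term $\rho\,\delta$ —
with the profile-overlap kernel $\chi(r;a)$:

$$\tilde g \;=\; \frac{\chi \circledast (\rho^2 g + \rho\,\delta)}{\rho^2}
 \;=\; (\chi \circledast g) \;+\; \frac{\chi(r)}{\rho}.$$

The kernel is the self-convolution of the uniform profile: a triangle
$(a-|r|)/a^2$ in 1D and, in 3D, the overlap volume of two balls of
diameter $a$ normalised to unit integral,
$\chi(r) = \frac{6}{\pi a^3}\bigl(1 - \tfrac32 y + \tfrac12 y^3\bigr)$,
$y = r/a < 1$.  Because the full-space integral of $\chi$ is one, the
infinite-volume integral of $\tilde g - 1$ equals that of $g - 1$ plus
$1/\rho$: the thermodynamic limit is untouched, whatever $a$.

Fluctuations in a subvolume of linear size $L$ (segment length in 1D,
sphere diameter in 3D) are then finite-volume Kirkwood–Buff integrals
with the geometric pair-distance weight $w(r;L)$:

$$\nu(L) = 1 + \rho \int_0^L w\,(g - 1)\,dr,
  \qquad
  \tilde\nu(L) = \rho \int_0^L w\,(\tilde g - 1)\,dr,$$

with $w = 2(1 - r/L)$ in 1D and
$w = 4\pi r^2\left(1 - \tfrac32 x + \tfrac12 x^3\right)$, $x = r/L$, in
3D.  The $+1$ in $\nu$ compensates the diagonal terms omitted from
$g$; in $\tilde\nu$ the diagonal is inside $\tilde g$ and the constant
is absent.  The "running KBI" — the same integral with $w$ replaced by
$2$ or $4\pi r^2$ — is provided only as a diagnostic: it oscillates,
goes negative (impossible for a variance), and diverges in crystals.

## Reference models

Everything is validated against systems with known answers.

**1D hard rods (Tonks).**  The equation of state
$\beta p = \rho/(1-\rho\sigma)$ gives the exact, size-independent
$\nu_\infty = (1-\rho\sigma)^2$.  The grand-canonical RDF is an exact
neighbour sum of shifted gamma densities (`tonks_rdf()`), and the
isobaric length moments `tonks_npt_moments()` reproduce the same
$\kappa_T$ for *any* particle number, to machine precision — the model
is the package's exactness anchor.

**3D hard spheres (Percus–Yevick).**  `py_rdf()` evaluates the Wertheim
analytic solution.  Two routes are provided:

* `method = "oz"` (default): Fourier inversion of the Ornstein–Zernike
  relation using the closed-form PY direct correlation function.  The
  sine transform is applied to $\gamma = h - c$, which is continuous
  everywhere, so the contact discontinuity never passes through the
  FFT; the route is uniformly accurate over the full tabulation range
  and reproduces the contact value $(1+\eta/2)/(1-\eta)^2$ and the
  zero-wavevector limit $(1-\eta)^4/(1+2\eta)^2$ to $10^{-6}$.
* `method = "shells"`: the piecewise-analytic shell expansion of the
  Laplace-space solution, evaluated by order-$n$ residue sums.  The
  two routes agree to better than $10^{-7}$ at moderate distances — a
  genuine dual-route check.  The shell route, however, is a victim of
  floating-point cancellation: the residue sums of shell $n$ combine
  terms that grow like $e^{t_0 (r-n)}$ ($t_0$ the real root of the
  Wertheim cubic) into an $O(1)$ answer, so beyond
  $r \approx 1 + 36/t_0\,\sigma$ double precision is exhausted — at
  $\rho = 0.7$ the expansion returns garbage past $r\sim 25\sigma$.
  That is why the OZ route is the default and the one used for
  production tabulations to $30\sigma$; `py_shell_rmax()` reports the
  reliable range of the expansion.

**FCC hard-sphere solid.**  At close packing the RDF is a delta comb on
the lattice shells (`fcc_shells()`, by direct enumeration).  The
modified RDF of the comb is evaluated analytically as a sum of shifted
kernels (`modify_shell_rdf()`) — no histogram binning — and is flat and
close to 1 away from a genuine diagonal peak $\chi(0)/\rho \approx
1.35$ at $r \to 0$.  For an immobile crystal the physically correct
fluctuation is exactly zero at every $L$; $\tilde\nu(L)$ stays below
$2\times10^{-3}$ on $L \in [2\sigma, 10\sigma]$ while the running KBI
oscillates with an envelope in the tens.

## Effective diameters

With the natural choice $a = \sigma$ the modified curve is nearly flat
at high filling but acquires a small $1/L$ tilt at low density.  The
profile diameter that removes the residual size dependence is slightly
smaller than $\sigma$:

$$a_1 = \sigma\,[1 - (1-\rho\sigma)^3] \quad(\text{1D}),
  \qquad
  a_3 = \sigma\,[1 - e^{-5.6\,\rho\sigma^3}] \quad(\text{3D}).$$

Both vanish as $\rho \to 0$ (the point-particle limit: an ideal gas
needs no excluded-volume correction) and approach $\sigma$ at liquid
densities; at $\rho\sigma = 0.8$ the 1D reduction is exactly $0.8\%$.
`effective_diameter_1d()` / `effective_diameter_3d()` evaluate them,
and the `corrected` profile option of the CLI uses them.

## Numerical choices

* **Grids.**  Uniform spacing, default $\Delta r = 10^{-3}\sigma$;
  $r_{\max} = 50\sigma$ (1D) and $30\sigma$ (3D).  Fitted intercepts
  move by less than $10^{-4}$ under $\Delta r$ halving.
* **The contact discontinuity.**  Hard-core RDFs jump at $r=\sigma$.
  The stored grid keeps the one-sided limit $g(\sigma^+)$ at the
  contact node; fluctuation integrals treat the core analytically
  (closed-form $\int_0^\sigma w\,dr$) and integrate the trapezoid only
  on $[\sigma, L]$, which keeps the quadrature second order.  Inside
  convolutions, which sample both sides of the jump, the contact node
  is averaged with the inside limit — the two half-cell errors then
  cancel.  Skipping either convention produces a first-order bias
  $\propto \rho\,(g(\sigma^+)+1)\,\Delta r$ in every intercept, large
  enough to corrupt the third decimal of $\nu_\infty$ at liquid
  densities.
* **Convolutions.**  The 3D radial convolution reduces to a 1D
  convolution of the odd extension of $r\,g(r)$ with the partial moment
  $k_1(u) = 2\pi\int_{|u|}^a t\,\chi(t)\,dt$; evaluated by FFT on the
  uniform grid, with $g$ extended by its hard-core zero below $\sigma$
  and by 1 beyond $r_{\max}$.  The diagonal term is always added
  analytically as $\chi(r)/\rho$, never convolved numerically.
* **Fits.**  $\nu(L) = \nu_\infty + C/L$ by ordinary least squares on
  a default window $[10\sigma,\ 0.8\,r_{\max}]$ ($\geq 10$ points
  enforced), with a stability report from a 20 %-shrunken window.
  The window matters at the $10^{-3}$ level because $\nu(L)$ carries
  higher-order ($1/L^3$-type) terms.

## What the Monte Carlo oracle does and does not emulate

`sample_tonks()` is an exact-constraint Metropolis sampler of hard rods
on a periodic ring, used as an *independent* route to the same
quantities: histogram RDFs against the analytic neighbour sum, and
direct window counting against the quadrature curves.  Discrete mode
counts rod centres; fractional mode assigns each rod a uniform profile
of length $a$ and adds exact interval-overlap fractions, realising the
continuous-$N$ picture by direct measurement, independent of the
convolution code path.  At $\rho\sigma = 0.8$ a window of only two
particle diameters returns $\hat\nu$ within a few $10^{-3}$ of the bulk
$\rho\kappa_T/\beta = 0.04$, while centre counting at the same size is
off by a factor of four — the package's headline demonstration.

The sampler is canonical (fixed $N$), standing in for the open-volume
picture; with the default box of $200\sigma$ and windows
$\leq 5\sigma$ the fixed-$N$ correction, the binomial factor
$(1 - L_w/L_{\rm box})$, is below the statistical resolution, and the
test suite applies that factor where it is resolvable.  The generator
emulates an equilibrium homogeneous hard-rod fluid only: no 3D
sampling (the PY closed forms play the oracle there), no attractive
interactions, no inhomogeneity.  Passing tests therefore certify the
machinery on athermal hard-core models, not the additional physical
size-dependence that attractive fluids can develop near phase
coexistence.

## Known limitations

* The modified RDF is for quantities defined through *integrals* of
  pair correlations (compressibility-type relations).  Point
  statements about $g$ — the contact theorem, cavity statistics
  $P(N)$, chemical-potential derivatives that need genuinely discrete
  counting — must keep the point-particle definition.
* The PY solution is itself approximate at high density; its
  compressibility route deviates from Carnahan–Starling by 1 % around
  $\eta \approx 0.16$ and increasingly beyond, so 3D results at
  $\rho \gtrsim 0.5$ inherit that model error.
* Only uniform (hard) profiles are implemented; soft or Gaussian
  profiles and per-species diameters for mixtures are out of scope.

## Worked example

```{r example, eval = FALSE}
sp  <- fluid_spec(rho = 1, sigma = 0.8, dim = 1)
rdf <- tonks_rdf(sp)
fit <- fit_asymptote(nu_curve(rdf))
c(exact = tonks_kappa(sp)$nu_inf, fitted = fit$nu_inf)
#>  exact fitted
#>   0.04 0.039997

nut <- nu_curve(modify_rdf(rdf, a = 0.8), seq(0.8, 16, by = 0.08))
range(nut$nu)     # flat at the exact value down to one particle size
#> [1] 0.0400 0.0443
```
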