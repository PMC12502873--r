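---
title: "Modelling membrane scattering with protein-like inclusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane scattering with protein-like inclusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsas)
```

## The model

`memsas` computes the elastic (SAXS/SANS) and inelastic (neutron spin-echo,
NSE) small-angle scattering of lipid membranes that carry transmembrane
protein inclusions, and fits the resulting models to reduced data. The
membrane is described through its space- and time-dependent scattering
length density (SLD) $\rho(\mathbf{x}, t)$; the observable is the
intermediate scattering function $I(q, \tau)$ per unit projected membrane
area, whose $\tau = 0$ slice is the elastic intensity.

Two membrane models are provided:

* a **static slab stack**: a piecewise-constant SLD profile $\rho(z)$ over
  layers (solvated outer layers, lipid heads of thickness $l_H$, a chain
  core of half-thickness $l_C$ per leaflet), whose rotationally averaged
  intensity is $I(q) = 2\pi\,|\hat\rho(q)|^2 / q^2$ with $\hat\rho$ the 1D
  Fourier amplitude of the solvent-contrasted profile. Finite stacks show
  the characteristic $q^{-2}$ law at low $q$.
* a **Gaussian fluctuating membrane**: the rigid stack displaced vertically
  by $h = l_\alpha W$, where $W$ is a unit-variance Gaussian field with
  space-time covariance
  $$g_W(r, \tau) = \frac{1}{1 + D\tau/l_{xy}^2}
    \exp\!\left[-\frac{r^2}{4 l_{xy}^2 (1 + D\tau/l_{xy}^2)}\right],$$
  i.e. Gaussian wave packets of lateral size $l_{xy}$ diffusing with
  coefficient $D$; each lateral Fourier mode decorrelates as
  $e^{-D k^2 \tau}$.

Proteins are modelled as infinite cylinders normal to the membrane plane
that intersect the stack: circular cross-sections of radius $R_p$ (or
randomly oriented ellipses for dimers), with per-layer protein SLDs
$\rho_p^{(n)}$ and an independent in-plane point process. For membrane and
protein structures that are statistically independent, the composite
correlation function is
$$C_\rho(\mathbf r, \tau) = C^{(a)}(\mathbf r, \tau)
  + C_p(r_{xy}, \tau)\, C^{(c)}(\mathbf r, \tau),$$
where $C^{(a)}$ and $C^{(c)}$ are the membrane correlations evaluated with
the layer SLDs replaced by the protein-weighted *average*
$(1-\phi_p)\rho^{(n)} + \phi_p \rho_p^{(n)}$ and by the *contrast*
$\rho^{(n)} - \rho_p^{(n)}$, and $C_p$ is the correlation function of the
protein cylinder phase. This composition is exact under the independence
assumption and is verified in the test suite against sampled random fields.

Two in-plane statistics are implemented:

* **hard discs** (elastic only): $I_p = \theta_p A_p^2 P_p(q_{xy})
  S_{HD}(q_{xy})$ with the disc form factor
  $P_p = [2 J_1(q R_p)/(q R_p)]^2$ and a low-density structure factor
  $S_{HD}(q) = [1 + 4\phi_p\, 2J_1(2 q R_{hd})/(2 q R_{hd})]^{-1}$, the
  direct-correlation closure truncated at the excluded-area term. It obeys
  $S_{HD} \to 1$ for $\phi_p \to 0$ and $q \to \infty$ and suppresses the
  $q \to 0$ limit ($S_{HD}(0) = 1/(1+4\phi_p)$). It is reliable for
  $\phi_p \lesssim 0.5$ and is isolated behind a single function so that a
  higher-order closure can be substituted.
* a **Boolean model** (elastic and dynamic): discs centred on a Poisson
  process of intensity $\theta_p$, allowed to overlap, with covered
  fraction $\phi_p = 1 - e^{-\theta_p A_p}$ and covariance
  $C_p(r, \tau) = (1-\phi_p)^2\,[e^{\theta_p K(r,\tau)} - 1]$, where
  $K(r, 0)$ is the geometric covariogram (lens area) of the cross-section
  and time enters by convolving $K$ with the isotropic Gaussian
  displacement law of per-axis variance $2 D_p \tau$.

In the dilute limit the two models agree; the leading Boolean correction is
*not* negligible at the per-mille level: the covariance constraint
$C_p(0,0) = \phi_p(1-\phi_p)$ forces
$C_p = \theta_p K\,[1 - \tfrac{3}{2}\theta_p A_p + O((\theta_p A_p)^2)]$,
so at $\theta_p A_p = 0.01$ the in-plane intensity deviates from
$\theta_p A_p^2 P_p$ by about 1.8% in sup-norm while the *normalized*
patterns agree to well below 1%. The test suite asserts this linear
scaling with its measured coefficient.

## Evaluation strategy

The slab path works entirely in reciprocal space: the protein term is the
orientation average
$\tfrac12 \int_{-1}^{1} d\mu\, |\hat\rho^{(c)}(q\mu)|^2
I_p(q\sqrt{1-\mu^2}, \tau)$, computed by Gauss-Legendre quadrature (order
64 with an order-doubling convergence check; the integrand is smooth and
band-limited over the instrument range).

For the Gaussian membrane the fluctuation statistics admit an exact
Hermite (Mehler) expansion: the lag-$\tau$, lateral-lag-$r$ covariance of
the displaced profile has the $r_z$-Fourier transform
$$|\hat\rho(q_z)|^2 e^{-q_z^2 l_\alpha^2}
  \sum_{k\ge1} \frac{(q_z l_\alpha)^{2k}}{k!}\, g_W(r,\tau)^k ,$$
and each power $g_W^k$ has a closed-form lateral Hankel transform. The
series terms are Poisson weights $e^{-x} x^k / k!$ with
$x = (q_z l_\alpha)^2$, so the truncation order is set adaptively to
$x + 12\sqrt{x+1} + 15$ and the evaluation is numerically stable at all
accessible $q$. With proteins, the lateral transforms
$H_k(q_{xy}) = \int 2\pi r J_0(q_{xy} r)\, C_p(r,\tau)\, g_W(r,\tau)^k\, dr$
are evaluated by a single Bessel-matrix quadrature (trapezoid on
$r \in [0, \max(8 l_{xy} + \text{diffusive broadening}, 12 R_p)]$ with 2048
nodes, cached across calls) and the $k$-sum reuses the same Poisson
weights; $H_0$ is the plain in-plane intensity, so the $l_\alpha \to 0$
limit reduces exactly to the slab path.

The same machinery yields the NSE observable. The neutron contrast of the
protein is weak (the protein contribution to the neutron intensity is two
orders of magnitude below the membrane contribution when integrated over
the fit range), so the NSE model uses the protein-corrected *average* SLDs
only; $I(q,\tau)/I(q,0)$ then decays monotonically from 1 towards the
plateau set by the average-structure share of the elastic intensity. The
approach to the plateau is slow (the lateral $k \to 0$ modes decay as
$e^{-Dk^2\tau}$), roughly as $\tau^{-1/2}$.

Real-space quantities are also exposed: one- and two-point layer
occupation probabilities (normal CDF differences and bivariate-normal
rectangle probabilities, the latter via conditional-normal Gauss-Legendre
quadrature with 128 nodes, accurate to ~1e-10), and the membrane
correlation function by z-quadrature on a grid with spacing
$\le \min(\text{layer thickness}, l_\alpha)/4$ extending $5 l_\alpha$
beyond the stack. A dedicated test transforms this real-space correlation
numerically and recovers the Hermite-series intensity to 2%.

## Parameters

| parameter | meaning | unit | reference value |
|---|---|---|---|
| `l_c` | chain half-layer thickness per leaflet | A | 16.3 |
| `l_h` | head layer thickness | A | 5.0 |
| `l_s` | protruding solvated layer | A | 0 |
| `rho_c, rho_h, rho_w, rho_p` | SLDs (chains, heads, solvent, protein) | 1/A^2 | see `rbc_sld_table()` |
| `r_p` | equivalent cylinder radius of the inclusion | A | 21.4 |
| `phi_p` | transmembrane protein area fraction | - | 0.23 |
| `l_alpha` | r.m.s. vertical membrane displacement | A | 23 |
| `l_xy` | lateral deformation size | A | 63 |
| `d` | wave-packet diffusion coefficient | A^2/ns | 1.85 |
| `d_p` | protein in-plane diffusion coefficient | A^2/ns | 0 |

The reference values describe red-blood-cell (RBC) membrane vesicles in
heavy water, with the band 3 anion transporter as the representative
inclusion: its 59 x 31 A elliptical cross-section maps to an equal-area
cylinder of radius 21.4 A, and the 23% transmembrane area fraction is the
literature estimate for RBC membranes. Band 3 dimers (105 x 31 A) are
supported through the randomly oriented ellipse form factor and
covariogram, with the hard-disc interaction radius identified with the
semi-major axis.

The derived correlation time of the membrane fluctuations is reported as
$\tau_c = l_{xy}^2/(4D)$ (the time for a packet to diffuse over its own
size; the factor 4 is the 2D mean-square-displacement rate), and every fit
report prints this defining formula next to the value rather than a bare
number, because the published value of the correlation time and the
printed $(l_{xy}, D)$ pair are not mutually consistent under any fixed
convention.

Two conventions are deliberately explicit rather than baked in:

* `slab_amplitude()` takes the reference SLD (void or solvent) as an
  argument, because the two contrasts answer different questions.
* the lateral-scale normalization of $g_W$ (the factor 4 in the Gaussian)
  fixes the meaning of fitted $l_{xy}$ and $D$; a different convention
  rescales both without changing the model's expressiveness. The
  roughness factor $E[\sqrt{1+|\nabla h|^2}]$ (per-axis slope variance
  $l_\alpha^2/2l_{xy}^2$, closed-form expectation of the exponential
  slope-squared distribution) is convention-dependent for the same
  reason: at the reference parameters it evaluates to about 1.06, of the
  same order as, but below, literature values near 1.2 obtained under
  steeper lateral-scale conventions.

## Synthetic data and what passing tests show

`make_fixtures()` generates the study datasets: elastic curves on a
100-point logarithmic grid over the instrument fit range
$q \in [8\times10^{-3}, 0.5]$ 1/A, and NSE tables at
$q \in \{0.036, 0.071, 0.109\}$ 1/A with 17 logarithmic lag times up to
200 ns (typical spin-echo window). Noise is multiplicative Gaussian at a
stated relative level (2% elastic, 5% NSE by default, matching good
reduced data), with $\sigma = \text{noise} \times I$ recorded in the
third column; $\tau = 0$ NSE rows are written as exactly 1 because the
measured ISF is normalized per $q$. The generator emulates the
*statistical structure* of reduced data - smooth model curves plus
independent heteroscedastic noise - but not instrument resolution
smearing, incoherent backgrounds beyond a flat term, multilamellar
contamination, or reduction artefacts; parameter-recovery results
therefore demonstrate estimator correctness, not robustness to those
systematics.

The stochastic realization module is the package's independent oracle: it
synthesizes periodic height fields spectrally (exact lattice covariance,
Ornstein-Uhlenbeck mode evolution), samples Boolean discs with Brownian
motion, voxelizes the composite SLD (exact partial-volume averages in z,
supersampled protein coverage laterally) and bins the 3D FFT intensity
into q shells. Comparisons against the analytic intensities co-average the
model's 3D mode intensity over exactly the same discrete modes - for the
Gaussian membrane via per-$q_z$ lattice DFTs of the clipped-profile
statistics - so that shell binning, finite box, and voxel filtering do not
bias the test. The default comparison grid spans $q \le 0.15$ 1/A with a
512 A box, 4 A lateral voxels and 1 A vertical voxels: above that range
the lateral rasterization of the protein phase limits oracle fidelity to
about 1%, while the membrane's structural features all lie inside it.
Tests assert agreement within 3 Monte-Carlo standard errors over 24 seeds.

## Fitting

`fit_elastic()` minimizes $\sum_i [(I_{model} - I_{obs})/\sigma_i]^2$
(weights $1/I$ when no uncertainties are supplied - reduced instrument
reduced data always carry them) over the geometric parameters, with the
per-dataset intensity scale and optional flat background profiled out
analytically at every step (they enter linearly), bounded
Levenberg-Marquardt underneath, and 5 seeded multi-starts. Joint fits
share the geometry across radiations and switch SLD tables per dataset.
Uncertainties come from the curvature of the profiled objective at the
optimum (Jacobi-scaled to tolerate the wildly different parameter
scales), scaled by $\chi^2/\text{dof}$. `fit_nse()` is the one-parameter
analogue for $D$ over a full $(q, \tau)$ surface with all structural
parameters fixed, as in the published protocol.

Numerical sizes were chosen to keep a joint two-dataset slab fit under ~3 s
and a Gaussian joint fit under ~1 min: the orientation average uses 32
nodes inside fits (64 outside), the in-plane intensity is evaluated once
per protein model on a 512-point grid and interpolated, and the Bessel
quadrature matrix is cached with the radial extent quantized upward to
128 A steps so nearby $l_{xy}$ iterates reuse it.

## Worked example

```{r example, eval = FALSE}
b <- symmetric_bilayer(l_c = 16.3, l_h = 5, rho_c = -0.07e-6,
                       rho_h = 1.87e-6, rho_w = 6.37e-6)
p <- protein_spec(r_p = 21.4, rho_p = 1.685e-6, phi_p = 0.23)
q <- exp(seq(log(8e-3), log(0.5), length.out = 100))
res <- slab_intensity_with_proteins(b, p, q)
plot(res$total$q, res$total$i, log = "xy", type = "l",
     xlab = "q (1/A)", ylab = "I(q) per unit area")
lines(res$membrane$q, res$membrane$i, col = "blue")
lines(res$protein$q, res$protein$i, col = "darkgreen")
```

## Known limitations

* Instrument resolution smearing and multilamellar Bragg peaks are out of
  scope; curves are "infinitely sharp" per-unit-area intensities with an
  arbitrary scale relative to absolute units.
* Compression (thickness) fluctuations are not modelled; the Gaussian
  membrane bends as a rigid stack.
* The hard-disc structure factor is a low-density closure; beyond
  $\phi_p \approx 0.5$ it is flagged and should not be trusted.
* Protein positions are independent of membrane curvature by construction;
  curvature-coupled partitioning is outside the composition rule.
* The hard-disc path has no dynamics; time-dependent protein statistics
  require the Boolean model.
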