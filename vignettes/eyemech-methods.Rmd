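---
title: "Models and numerical methods in eyemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in eyemech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`eyemech` models the mechanics of the eye wall (cornea, sclera, lamina
cribrosa) under elevated intraocular pressure (IOP). It covers four
stages: (1) a hyperelastic--viscoelastic constitutive law for
incompressible ocular tissue; (2) forward simulation of uniaxial
strip-tension experiments and inverse identification of the material
constants from multi-rate force--displacement curves; (3) a parametric,
heterogeneous-thickness eyeball shell mesh; (4) a quasi-static membrane
solver producing equivalent stress/strain fields at glaucoma-relevant
IOP levels, with per-region summaries. A synthetic-data module makes the
whole chain testable without any measured input.

# Constitutive model

The tissue is incompressible and isotropic. The equilibrium response is
a one-term Ogden solid: in uniaxial stretch $\lambda$ with transverse
stretches $\lambda^{-1/2}$,

$$W(\lambda) = \frac{\mu}{\alpha}\left(\lambda^{\alpha}
  + 2\lambda^{-\alpha/2} - 3\right), \qquad
\sigma_{\mathrm{hyper}}(\lambda) = \mu\left(\lambda^{\alpha}
  - \lambda^{-\alpha/2}\right),$$

with exponent $\alpha$ (dimensionless) and modulus $\mu$ (MPa). The
volumetric penalty term of the general compressible form is dropped
identically because $J \equiv 1$. Rate dependence is a single-exponential
hereditary integral (Christensen-type quasi-linear viscoelasticity),

$$\sigma_v(t) = \int_0^t G\, e^{-\beta (t-\tau)}
  \frac{\partial\varepsilon}{\partial\tau}\, d\tau,$$

with relaxation modulus $G$ (MPa) and decay rate $\beta$ (1/s); the
total uniaxial stress is the sum of both parts. Identified bovine
values (`bovine_eye_materials()`): sclera $\alpha = 27.7$,
$\mu = 0.774$ MPa, $\beta = 0.93$ /s, $G = 1.8$ MPa; cornea
$\alpha = 8.1$, $\mu = 0.675$ MPa, $\beta = 0.13$ /s, $G = 1.641$ MPa.

Three conventions had to be fixed because the source measurements do not
pin them down, and each is isolated and configurable:

* **Strain in the hereditary integral.** Engineering strain
  $\varepsilon = \lambda - 1$ by default (`deformation_history()`
  accepts `"logarithmic"`). The identified $(\beta, G)$ are only
  meaningful together with this choice.
* **Stress measure.** The Ogden uniaxial formula is read as Cauchy
  (true) stress, the conventional uniaxial reduction; the tensile module
  therefore converts stress to force through the *current* cross-section
  $A(t) = A_0/\lambda$.
* **Units of $\beta$.** 1/s, consistent with crosshead speeds in mm/s.

The convolution is advanced by the exact-exponential recursion
$\sigma_v(t_{k+1}) = e^{-\beta\Delta t}\sigma_v(t_k) +
G\,\Delta\varepsilon_k\, e^{-\beta\Delta t /2}$ (midpoint kernel),
unconditionally stable and second order. The test suite checks it
against an independent $O(n^2)$ direct quadrature (relative agreement
$10^{-8}$) and against the constant-rate closed form
$(Gr/\beta)(1 - e^{-\beta t})$.

# Strip tension, forward and inverse

Strips are modelled as homogeneous uniaxial continua:
$\lambda(t) = 1 + vt/L_0$, with force
$F = \sigma A_0 / \lambda$. For a uniform strip this closed form equals
a meshed FE solution of the same law, and gives an exact, fast kernel
for the inverse loop. Strip thickness is not part of the printed
protocol: defaults are 1.7 mm (sclera; mid-range of the 1.55--1.86 mm
wall measured near the optic papilla) and 0.8 mm (cornea).

The displacement amplitude is likewise unprinted. The package default
for scleral strips is 0.75 mm (peak stretch $\approx 1.05$), chosen so
the quasi-static peak force is $\approx 17$ N, matching the reported
order (16 N at the lowest rate). An amplitude giving $\lambda = 1.15$
would predict peak forces of 200--400 N with the identified
$\alpha = 27.7$ -- two orders above the reported curves -- so the
smaller amplitude is the only choice consistent with the stated peak
forces. Corneal strips use 1.5 mm ($\lambda = 1.15$, $\approx 12$ N),
which is consistent as printed. Rates default to 0.3/3/30/300 mm/s
(sclera) and 0.3/30 mm/s (cornea); the lowest rate is 0.3 mm/s (one
passage reporting "0.03 mm/s" conflicts with the stated protocol and is
treated as a typo).

**Inverse identification** (`nsga2_fit()`) minimizes one force-RMSE
objective per loading rate with NSGA-II (population 100, 100
generations, simulated binary crossover $p_c = 0.9$, $\eta_c = 15$,
polynomial mutation $p_m = 1/4$, $\eta_m = 20$), initialized by a Sobol
design of experiments over the bounds box $\alpha \in [1, 60]$,
$\mu, \beta, G \in [0.01, 10]$ (at least twofold margins around the
identified values; the sources cite "pertinent literature" without
numbers). The reported parameter set is the final-population member with
the minimum equally weighted RMSE sum.

*Hybridization.* Pure coordinate-wise genetic operators stall in this
problem: $(\alpha, \mu)$ and $(\beta, G)$ each lie in a strongly
correlated, shallow objective valley, and with four near-degenerate
objectives the population stops improving near a summed RMSE of
$10^{-2}$ N -- leaving $\beta$ and $G$ essentially unidentified. The
engine therefore applies a deterministic Nelder--Mead refinement to the
minimum-sum member every 10 generations (Lamarckian re-injection). This
is standard practice in engineering identification, keeps the run
deterministic given the seed, and preserves the invariants (the best
member belongs to the final population; the returned front is mutually
non-dominated; the generation-best summed RMSE is non-increasing). With
it, all four constants are recovered exactly from noiseless 4-rate
data in 10/10 seeds; without it, 0/10 seeds meet even 15% on $G$.

Identifiability behaves as theory predicts: a single quasi-static curve
constrains only $(\alpha, \mu)$ -- the objective is flat across the
whole $(\beta, G)$ box (verified by a brute-force profile) -- while
multi-rate data pin all four.

# Synthetic data

`gen_tensile_dataset()` adds i.i.d. Gaussian force noise (default SD
0.2 N, about 1% of the scleral peak force; measurement error of a
servo-hydraulic load cell at this scale) to forward-model curves; it is
a pure function of its parameters and seed. `gen_lc_table()` draws
per-eye lamina cribrosa axes from zero-truncated Gaussians rounded to
0.01 mm (caliper resolution), with the 8/8/4 age design and the
measured mean/SD per axis. The bundled 20-eye table is in-study data
shipped as a text fixture; its printed naso-temporal summary matches the
population-SD (n denominator) convention, which is therefore the
default in `lc_summary_stats()` (the longitudinal SD prints as 0.109
while the rows compute to 0.110 -- recorded as a known inconsistency,
not forced to match). What the generator does *not* emulate: toe-region
slack, grip slippage, preconditioning, hydration drift, or heavy-tailed
noise; a green recovery test therefore establishes correctness of the
identification machinery, not robustness to every laboratory artifact.

# Eye geometry

The globe is an equiangular cubed-sphere quadrilateral shell (radius
15 mm by default), which avoids polar slivers: the default mesh
(refinement 24, 3456 facets, ~1 mm elements) has minimum scaled
Jacobian 0.87 and minimum angle 62 degrees, comfortably above the 0.47 /
43.53-degree report thresholds carried over from the reference
hexahedral model (those thresholds are configurable flags, not
assertions). Regions are assigned by facet centroid: a corneal cap of
half-angle 40 degrees at the anterior pole; an elliptical lamina
cribrosa patch at the posterior pole with the morphometry-mean axes
4.60 x 3.68 mm; anterior/posterior sclera split at the equator.

Thickness is heterogeneous -- the point of the modelling exercise:
sclera varies linearly in polar angle from 1.0 mm at the limbus to
1.7 mm at the posterior pole; the LC plate is 0.4 mm; the cornea thins
centrally, from 0.8 mm at the apex growing linearly to the limbal
1.0 mm so the wall is continuous. The central corneal thinning is an
anatomical default with a mechanical consequence worth stating: on a
sphere a *uniform* cap produces a membrane stress field constant to a
few percent ($\sigma \approx pR/2t$), so "where is the corneal peak" is
then decided by discretization noise; with central thinning the central
concentration reported for the cornea is a physical prediction.
Bovine globe radius and corneal thickness are not printed anywhere in
the source measurements; both are declared assumptions, swept in tests
rather than asserted.

The shell (surface + per-facet thickness) replaces the solid hexahedral
scan-based model deliberately: the wall is thin relative to the globe,
the load is pressure on the inner wall, and a shell admits an analytic
thin-sphere oracle. Image-derived geometry is out of scope.

# Pressurization solver

Static equilibrium under uniform internal pressure applied
perpendicular to the deforming inner wall (follower load) is solved by
dynamic relaxation: constant-strain-triangle membrane kinematics (quads
split internally), incompressible Ogden response in plane stress
($\sigma_i = \sum_j \mu_j(\lambda_i^{\alpha_j} -
(\lambda_1\lambda_2)^{-\alpha_j})$), consistent nodal forces as exact
energy gradients (verified against finite differences to $10^{-9}$),
stiffness-proportional nodal pseudo-masses, kinetic damping (velocities
zeroed at kinetic-energy peaks), and convergence at residual
$< 10^{-6}$ of the load resultant. Rigid translation is pinned by a
weak centroid spring that carries no force at convergence (a closed
pressure load has zero resultant). The steady state uses only the
hyperelastic part: the exponential kernel decays, so static equilibrium
is rate-independent. A quasi-static ramp mode (`ramp_steps > 1`)
carries the viscoelastic convolution across pressure increments for
transient studies and relaxes to the static solution for slow ramps.

Equivalent stress is the von Mises invariant of the membrane stress
($\sqrt{\sigma_1^2 - \sigma_1\sigma_2 + \sigma_2^2}$ in plane stress);
equivalent strain is the von Mises-type invariant of the logarithmic
principal strains with $\varepsilon_3 = -(\varepsilon_1 +
\varepsilon_2)$. The oracle: a uniform near-linear sphere reproduces
Laplace's law $\sigma = pR/2t$ within 0.3% at the default refinement
(asserted at 5%). IOP levels follow the glaucoma ladder 10/30/60/100
mmHg (1 mmHg = 133.322 Pa).

The lamina cribrosa has no independently identified constants; it
defaults to scleral parameters with moduli scaled by 0.5
(`lc_material()`), a declared assumption reflecting the porous plate's
higher compliance. Because the LC is also 4x thinner than the
surrounding wall, its stress concentration (and its central peak) is
robust to this factor.

# What the qualitative tests establish

At the default configuration the suite asserts, per IOP level: the LC
peak equivalent stress lies in the central 50% (by area) of the LC
ellipse; the corneal peak lies in the central 50% of the cap; and the
posterior-sclera area fraction in the lowest whole-globe stress
quartile does not shrink as IOP rises. The third statement is
geometry-dependent; on this idealized globe it holds degenerately (the
fraction saturates at 1: the whole-globe stress range is dominated by
the thin LC, and the entire thick posterior sclera sits in the lowest
band). It is reported as computed, not tuned. Absolute stress maps of
the scanned-geometry study are not reproducible at desk scale and are
not asserted.

# Numerical choices and limitations

* Sobol points are generated from standard direction numbers
  (dimensions 1--10), enough for the 4-parameter identification; the
  first point is the canonical (0.5, ...).
* Ties in non-dominated sorting are broken by crowding distance, then
  candidate index; all randomness flows from one seed, so every fit and
  pipeline run is bit-reproducible.
* Non-finite objective values (e.g. overflow at extreme $\alpha$) are
  penalized, not fatal; an all-non-finite population is an error.
* The membrane model omits bending: wrinkling-dominated or
  locally-indented states are outside its validity. Contact,
  fluid--structure interaction and optic-nerve tethering are out of
  scope.
* The pipeline manifest records an MD5 per artifact so silent
  nondeterminism is detectable by rerunning with the same seed.
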