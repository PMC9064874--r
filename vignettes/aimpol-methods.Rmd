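---
title: "Methods: atom-in-material polarizabilities and dispersion coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atom-in-material polarizabilities and dispersion coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimpol)
```

## The problem and the model

A molecule's polarizability is a many-body property: directional
dipole–dipole coupling between atoms creates contributions that isolated
atoms do not have. `aimpol` starts from per-atom descriptors produced by a
stockholder partitioning of the electron density — electron count $N_A$,
net charge $q_A$, radial moments $\langle r^3\rangle$ and
$\langle r^4\rangle$, AIM volume $V_A$, an exposure factor $m_A$, and a
damping radius — and produces three per-atom polarizability types with
distinct physical meanings:

* $\alpha^{\mathrm{force\text{-}field}}$ — screened only through the
  orientation-*independent* channel. Polarizable force fields must use
  this value: the simulation itself re-introduces directional coupling,
  and any directionally screened input would double-count it.
* $\alpha^{\mathrm{static}}$ (a symmetric tensor) — response to a uniform
  applied field, including directional coupling at full strength.
* $\alpha^{\mathrm{low\_freq}}$ / $\alpha^{\mathrm{screened}}(u)$ —
  fluctuating-dipole polarizabilities in which directional alignment decays
  with distance; these feed the Casimir–Polder integral for $C_6$.

The assumptions worth keeping in mind: per-atom response is represented by
spherical Gaussian dipoles (anisotropy enters only through the coupling,
which is why a small anisotropy correction is applied at the end); dynamic
polarizabilities are one-Lorentzian in the imaginary frequency; and all
descriptors are taken at face value from the partitioning code — the
package never recomputes densities.

## Unscreened atoms: scaling laws and m-scaling

Free-atom polarizabilities are *not* proportional to
$\langle r^3\rangle$ across elements. The package therefore uses fitted
log-linear scaling laws in $N$, $\langle r^3\rangle$ and
$\langle r^4\rangle$ (coefficients in `scaling_coefficients()`), applied as
ratios to a neutral free-atom reference so that the reference atom itself
is reproduced exactly. Under a uniform scaling of the atom's radius the
fitted laws give $\alpha \propto r_{\mathrm{eff}}^{3.8517}$ (close to the
theoretical 4th power) and $w_p \propto r_{\mathrm{eff}}^{-1.7903}$ (close
to $-2$).

Buried atoms behave differently: condensed-phase polarizability is
approximately proportional to volume. The exposure factor
$m \in [0,1]$ ($1$ = isolated, $\to 0$ = deeply buried; computed by
`exposure_m()` as the density-weighted average of the spherically averaged
stockholder weight fraction when profiles are available, or supplied
directly) interpolates geometrically:
$$\alpha^{\mathrm{unscreened}} =
  (C\langle r^3\rangle)^{1-m}\,\Omega^{m}, \qquad C = 0.4,$$
where $\Omega$ is the isolated-atom scaling-law value. The characteristic
frequency uses
$w_p = \zeta^{(1-m^2)/4}\,\gamma\,w_p^{\mathrm{ref}}$ with $\gamma$ the
isolated-atom law ratio; for $\zeta$ this package uses the dimensionless
ratio $\Omega/(C\langle r^3\rangle)$ between the two limiting laws — the
only dimensionless group the inputs provide; at $m = 1$ the exponent
vanishes, so every isolated-atom property is independent of this choice,
which damps the sensitivity of $w_p$ for buried atoms as intended.

## The conduction bound and the smooth minimum

No electron cloud at fixed nuclei out-polarizes a perfect conductor. The
local polarizability-to-volume ratio of a conducting plate is $1/(2\pi)$
(atomic units), giving the per-atom cap $\alpha \le V_A/(2\pi)$ applied
after non-directional screening (the plate's *overall* ratio, $1/(4\pi)$,
and the conducting sphere's $3/(4\pi)$ are shape-dependent and belong to
directional response; `conduction_reference()` exposes the sphere form for
benchmarking). The cap is imposed by a smooth minimum so that forces stay
continuous:
$$\mathrm{smooth\_min}(a,b) =
  \frac{a\,e^{-\Upsilon a/b} + b\,e^{-\Upsilon b/a}}
       {e^{-\Upsilon a/b} + e^{-\Upsilon b/a}}, \qquad \Upsilon = 25,$$
returning 0 when either argument is non-positive. This form is
scale-invariant (the deviation depends only on $b/a$), exact at $a = b$ and
in the extreme-ratio limit, and its worst relative deviation from
$\min(a,b)$ — attained near $b/a \approx 1.026$ — is 0.56 %, within the
0.58 % band the steepness value was chosen for. Simple inverse-power-mean
alternatives deviate by ~2.7 % at the same steepness and were rejected.

## Screening: channels, increments, widths

The Gaussian-damped dipole interaction between atoms $A$ and $B$ is
$\tau = -\nabla\nabla\,\mathrm{erf}(d/\sigma_{AB})/d$ with per-atom widths
$\sigma_A = (\sqrt{2/\pi}\,\alpha_A/3)^{1/3}$ combined in quadrature. Its
trace part ($\tfrac13\mathrm{Tr}\,\tau$, a short-range Gaussian-overlap
term; the bare point-dipole tensor is traceless) defines the
*non-directional* channel, screened on $N\times N$ matrices; the traceless
remainder defines the *directional* channel, screened on $3N\times 3N$
matrices — once at full strength for the static tensor and once multiplied
by the multibody attenuation
$\exp[-d/(\mathrm{MBSP}\,(r_{\mathrm{damp},A}+r_{\mathrm{damp},B}))]$,
$\mathrm{MBSP} = 2.5$, for the fluctuating polarizabilities. First-order
exponential decay is the natural alignment model (half the alignment
surviving $d_{1/2}$ means a quarter survives $2d_{1/2}$); the sum of the
two unscreened damping radii is the natural symmetric pair length scale.

Interactions are turned off smoothly at $d_{\mathrm{cutoff}} = 50$ bohr by
$f_{\mathrm{cutoff}}(d) = H(d_c - d)\,[1 - e^{-20((d_c-d)/d_c)^3}]$, which
keeps first and second derivatives continuous at the cutoff and stays
$\ge 0.9179$ inside half the cutoff. The TS-SCS baseline uses a hard
cutoff, consistent with prior practice for that method.

Screening is applied *incrementally*: $Q_{j+1} = D_j + \Delta_j\tau_j$,
where $D_j$ holds the current inverse per-atom polarizabilities
(tensors in the directional stages), $\tau_j$ is rebuilt each iteration
with widths from the current polarizabilities, and the increments
$\Delta_j$ sum to 1. The default schedule is 10 equal increments for every
stage; the test suite verifies that doubling the count changes static
results by less than $5\times10^{-4}$ relative on a close dimer, and a
single increment with frozen widths reproduces a one-shot dense solve
exactly. (A fancier extrapolated schedule could replace this; the equal
schedule keeps the iteration transparent and is converged at desk scale.)
After each inversion the mixed $A$–$B$ blocks are assigned
*proportionally* to the atoms' pre-screened polarizabilities rather than by
Applequist row sums; this conserves the system total, guarantees symmetric
per-atom tensors, and removes the negative-polarizability pathology the
row-sum contraction can produce for extreme-contrast pairs (the TS-SCS
baseline deliberately retains the row-sum behaviour, and the test suite
exhibits the sign failure on a synthetic K–He dimer). If both weights of a
pair vanish — a measure-zero situation — the split falls back to 50/50
with a warning.

The static tensors finally receive the anisotropy correction
$\mathrm{C.F.}\,\alpha^{\mathrm{iso}} I + (1-\mathrm{C.F.})\,\alpha$,
$\mathrm{C.F.} = 0.2$: the spherical-dipole model under-screens along easy
axes and over-screens along hard ones, inflating anisotropy; mixing 20 %
of the isotropic value back in compensates while preserving the trace.

## Frequency grid and Casimir–Polder integration

Imaginary frequencies are mapped to an integer grid $u = 1..16$ via
$\omega(u) = \Lambda[(N/u)^2 - 1]$, $\Lambda = 0.1$ hartree, so the static
point is $u = N$ and the integrand of
$C_6 = \tfrac{3}{\pi}\int \alpha(i\omega)^2 d\omega$ vanishes at $u = 0$.
Classical Romberg extrapolation over the 17 equally spaced nodes then
integrates it. $\Lambda$ is a pure numerics knob: it places quadrature
nodes, not physics. The value 0.1 was selected (once, against the
closed form $\tfrac34\alpha_0^2 w_p$) to give $\le 0.11\%$ error for
Lorentzian profiles with $w_p \in [0.05, 1]$ hartree — the physical range
of elemental characteristic frequencies — comfortably inside the 1 % the
method needs from its 16-point rule.

Heteroatomic $C_6$ uses the Padé/London mixing rule
$C_{6,AB} = 2C_{6,A}C_{6,B}/[(\alpha_B/\alpha_A)C_{6,A} +
(\alpha_A/\alpha_B)C_{6,B}]$ with $\alpha^{\mathrm{low\_freq}}$, which is
*exact* for two one-Lorentzian species (verified against adaptive
quadrature in the tests). Molecular $C_6$ between two molecules sums
$C_{6,AB}$ over the memberships; the single-molecule self-$C_6$ convention
here includes the $A = B$ diagonal of the double sum (both conventions are
trivially interconvertible; the choice is fixed and tested).

## QDO block

Each atom's quantum Drude oscillator is fixed by
$w_p^{\mathrm{QDO}} = 4C_6/(3\alpha^2)$,
$m^{\mathrm{QDO}} = \tfrac{15}{2}\alpha^2/C_8$ and
$q^{\mathrm{QDO}} = w_p\sqrt{m\alpha}$, where $\alpha$ is the force-field
polarizability, $C_6$ the non-directional coefficient, and $C_8$ comes
from the fitted correlation
$C_8 = e^{1.7327} C_6^{\mathrm{non\text{-}dir}}
(\langle r^4\rangle/\langle r^3\rangle)^{0.8305}$ (a fit with ~15 % mean
absolute relative error against correlated references — adequate for the
~25 % contribution $C_8$ makes to well-depth attraction). Multipole
polarizabilities follow
$\alpha_l = \alpha_1[(2l-1)!!/(2m w_p)]^{l-1}$ with the $l$-pole resonance
at $l\,w_p$ (an $l$-quantum excitation of the oscillator), and all pair and
triple coefficients are closed-form Casimir–Polder integrals of these
Lorentzians — e.g. homoatomic $C_8 = 5w_p\alpha_1\alpha_2$ and the
Padé-type triple-dipole rule for $C_{9,ABC}$. Every closed form is
cross-checked against independent numerical quadrature in the tests.
$C_9$ output is labelled for intermolecular use only: directionally
screened $C_6$ already contains the intramolecular triple-dipole coupling.

## Synthetic data: what it shows and what it cannot

The package ships no quantum-chemistry data. `make_toy_system()` builds
dimers, chains and periodic cubic lattices whose AIM descriptors are
reference-atom moments times controllable perturbation factors, with
exposure factors set directly (gas-phase toys use $m = 1$, lattice toys
$m \approx 0.1\text{–}0.3$) and geometric van-der-Waals-scale volumes. The
bundled reference table anchors free-atom $\alpha$ and $C_6$ to standard
literature values for ~25 common elements but carries *synthetic* radial
moments and damping radii (clearly labelled in the file); production use
should substitute a real reference table of the same schema.

Consequently the test suite establishes the method's *internal* contracts —
limits, conservation laws, symmetry, oracle equivalence, positivity on
hundreds of randomized toys, printed-value arithmetic — on systems small
enough to run in seconds (dimers to 27-atom periodic lattices, 2–16
frequency points). It does not, and cannot, establish accuracy against
experimental polarizabilities of real solids or molecules: that requires
partitioned densities from a quantum-chemistry code, which are consumed,
never computed, here.

## Degenerate inputs and edge behaviour

Non-positive moments, volumes, or mixing weights are rejected with typed
errors (`invalid-value`, `invalid-moment`, `consistency-error`, ...);
electron counts must satisfy $N = Z - q$ to $10^{-4}$ (tables printed at
~6 significant figures pass, genuine inconsistencies do not). Singular
screening matrices raise `screening-singularity` with the iteration index.
A single atom short-circuits every stage (screening is a no-op).
`smooth_min` returns exactly 0 when either argument is $\le 0$, which also
protects the pipeline if a pathological input drives a raw screened value
negative. Widths are floored at $10^{-10}$ bohr³-equivalent purely to keep
cube roots finite.

## Known limitations

* The screening solves dense $3N\times3N$ systems; fine for desk-scale
  systems (hundreds of atoms), not for the linear-scaling regime.
* One Lorentzian per atom in $\omega$; multi-oscillator dynamic responses
  are outside the model.
* Dispersion *energies*, damping functions for DFT+D, and many-body
  dispersion energy models are out of scope: the package parameterizes,
  it does not sum lattice energies.
* Exposure factors from full 3D densities are the partitioning code's job;
  `exposure_m()` only integrates pre-tabulated spherical profiles.
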