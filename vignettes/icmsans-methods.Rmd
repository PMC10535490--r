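---
title: "Methods: inverse contrast-matching SANS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse contrast-matching SANS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmsans)
```

This vignette documents the physical model behind each stage of the
package, the choice of numerical methods and default parameters, the
design of the synthetic-data generators, and the known limitations. All
problem sizes quoted below (cluster sizes, bead counts, grid resolutions)
are the package's own defaults, chosen to balance statistical quality
against a few seconds to a few minutes of desktop compute.

## 1. Scattering-length densities and contrast

Coherent neutron scattering lengths are tabulated per element (with
deuterium as a separate entry, `scattering_length("D")` = +6.671 fm
against `scattering_length("H")` = -3.739 fm). A solvent of D2O volume
fraction $f$ has

$$\rho(f) = (1-f)\,\rho_{\mathrm{H_2O}} + f\,\rho_{\mathrm{D_2O}},$$

with the water SLDs computed from $\sum b / V$ at $V = 30$ Å$^3$ per
molecule ($-0.558$ and $+6.38 \times 10^{-6}$ Å$^{-2}$). Biomass
components are described by class-level stoichiometric formulas
(protein, nucleic acid, lipid, carbohydrate, other organics, inorganics)
with per-class labile-hydrogen counts; the default composition is an
*E. coli*-like 15:7:2:3:1:1 mass ratio. The component SLD at solvent
fraction $f$ includes non-exchangeable deuteration and labile hydrogens
that scatter as the mixture $(1-x) b_\mathrm{H} + x b_\mathrm{D}$ with
$x = f \times$ `exchange_efficiency` (default 0.9, reflecting incomplete
exchange in folded material).

Because SLD is additive per unit volume, multi-class compositions are
combined volume-weighted: mass fractions are converted to volume
fractions through each class's partial specific volume. For a
single-class composition this is identical to mass weighting.

The contrast-match point is the crossing of the component and solvent
SLD lines, solved from two evaluations because both sides are affine in
$f$. Crossings are accepted in $[-50, 200]\%$ D2O: values above 100%
are the *inverse contrast-matching* regime, where a deuterated component
can only be matched by extrapolation beyond pure D2O and therefore stays
matched (invisible) in any real solvent that exceeds its crossing only
virtually. `mixture_match_point()` combines two pools by volume using
the same affine algebra.

## 2. Reduction

`reduce_solute()` implements monitor- and transmission-normalized
background subtraction with the solvent-displacement correction,

$$I_{\mathrm{solute}} =
\left[\tfrac{I_{\mathrm{soln}}}{B T} - \tfrac{I_{\mathrm{cell}}}{B T}\right]
 - (1 - c v_a)
\left[\tfrac{I_{\mathrm{solv}}}{B T} - \tfrac{I_{\mathrm{cell}}}{B T}\right],$$

where $c$ is the solute concentration in g/cm$^3$ and $v_a$ its partial
specific volume (default 0.74 cm$^3$/g). Uncertainties propagate in
quadrature with coefficients $1$, $(1 - c v_a)$ and $c v_a$. The
reduction is validated by synthesizing raw counts from a known solute
curve and inverting them exactly.

## 3. Match-point estimation from a contrast series

For each solvent fraction the band $0.0065 \le q \le 0.009$ Å$^{-1}$ is
trapezoid-integrated and $v = \sqrt{I_{\mathrm{integ}}}$ fitted with the
kinked line $v = |a f + b|$, whose root $-b/a$ is the match point. The
absolute value captures the sign flip of the contrast across the match,
so series that never cross the match point still extrapolate correctly.
The fit enumerates every possible crossing segment, solves the
sign-flipped ordinary least squares in closed form, and keeps the best:
unlike gradient descent on the kinked objective this is exact on exactly
affine data. The incoherent solvent background does not follow the
contrast parabola, so paired solvent curves are subtracted first
(`subtract_solvent = TRUE`); skipping this measurably biases the
recovered match point.

## 4. Curve statistics

`porod_slope()` is an ordinary least-squares fit of $\log I$ against
$\log q$ inside a stated window; a mass-fractal dimension is only
reported when the slope lies in $(-3, -1)$. `detect_peaks()` first fits
a robust baseline $A q^p + c$ (Levenberg-Marquardt inside an iterative
reweighting loop that strongly downweights positive excursions, i.e.
candidate peaks), then reports local maxima of the residual exceeding
`min_prominence` times the baseline, with three-point parabolic position
refinement. `assign_harmonics()` tests fundamentals $q_i/n$ and prefers
the assignment that explains the most peaks, breaking ties toward the
largest fundamental so a repeat distance is never reported as twice its
true value. `bragg_spacing()` is $d = 2\pi/q$.

## 5. Debye simulator

The orientationally averaged intensity is the Debye double sum
$I(q) = \sum_{ij} b_i b_j \,\mathrm{sinc}(q r_{ij})$, computed exactly
up to `exact_limit` scatterers (default 2000) and above that through a
pair-distance histogram (default bin 0.5 Å) whose per-bin representative
distance is the weight-averaged distance; this keeps the acceleration
within 0.5% of the exact sum for $q < \pi/(2\,\mathrm{bin})$. Effective
per-atom lengths are the vacuum length, plus exchangeable hydrogens at
the solvent H/D mixture, minus $\rho_{\mathrm{solv}} V_{\mathrm{excl}}$
(the excluded-volume term; CRYSOL/CRYSON-style displaced-solvent
volumes). The engine is validated against the analytic sphere form
factor with a deterministic lattice-filled ball — a Monte Carlo fill
leaves percent-level noise concentrated at the form-factor minima,
which would blunt the oracle.

The hydration shell is sampled Shrake-Rupley style: candidate points on
a mid-shell sphere per atom, kept when not buried in a neighbour's
sampling sphere, each carrying scattering length
$(\text{factor}-1) \rho_{\mathrm{solv}} V_{\mathrm{point}}$ — a shell
10% denser than bulk solvent by default, 3 Å thick. In the
inverse-matching solvent (96.7% D2O) this shell scatters strongly, which
is why hydration must be modelled at all.

## 6. Fibril assemblies

`make_cross_beta_unit()` builds two flat beta sheets (strand spacing
4.7 Å, sheet separation 10 Å) of point scatterers;
`elongate()` stacks rigid copies along the fibril axis with optional
per-repeat twist (rotation about the axis through the unit centroid);
`lateral_pair()` places two copies side by side. The pair interference
is read from the ratio $I_{\mathrm{pair}}/I_{\mathrm{single}}$, whose
first maximum sits at the first maximum of $\mathrm{sinc}(qd)$,
$qd \approx 7.725$ — for $d = 250$ Å that is $q \approx 0.031$ Å$^{-1}$,
and the position shifts monotonically with separation.

## 7. Bead modelling

`bead_fit()` anneals occupancies on a touching-sphere hexagonal lattice
inside a search sphere. The energy is the reduced $\chi^2$ against the
target curve (with a free overall scale, profiled analytically) plus
`looseness_weight` times the fraction of occupied beads with fewer than
three occupied neighbours, which penalizes stringy, disconnected
solutions. Each Metropolis flip updates the model intensity
incrementally in C++, so a step costs $O(N_{\mathrm{beads}})$ rather
than $O(N^2)$. After annealing only the largest connected component is
retained. Reconstructions are compared with the normalized spatial
discrepancy (NSD), normalizing each set by its own mean nearest-neighbour
distance and minimizing over the 48 signed axis permutations after
centroid alignment; `ensemble_filter()` drops members whose mean NSD to
the rest exceeds a threshold (default 1.7, the conventional acceptance
cut for independent reconstructions).

## 8. Synthetic-data generators

Every generator is deterministic under a fixed seed and stores its
ground truth in the curve metadata, so each estimator is tested
closed-loop against known answers. `gen_debris_curve()` is a
Fisher-Burford-type mass-fractal profile plus incoherent level;
`gen_contrast_series()` scales the coherent term by the squared contrast
distance $((f - f_{\mathrm{mp}})/100)^2$ and pairs every curve with a
solvent-only curve whose incoherent level falls linearly with $f$
(H2O dominates incoherent scattering); `gen_fibrillization_timecourse()`
drifts the background slope from $-2.4$ to $-2.5$, grows first- and
second-order interference peaks after an onset time, and adds the broad
beta-stacking hump at 0.4 Å$^{-1}$.

`gen_dla_cluster()` grows off-lattice 3D diffusion-limited aggregates of
touching hard spheres: walkers launch from a sphere just outside the
cluster, take steps of one monomer radius (with exact spherically
symmetric long jumps while far outside the envelope, which cannot change
first-contact statistics), and stick at their exact first intersection
with any contact sphere along the step segment. This guarantees touching
without overlap; the generator's nearest-neighbour distances equal the
contact distance to machine precision.

## 9. Fractal scattering of finite aggregates: a caveat

The asymptotic mass-radius dimension of these aggregates is the textbook
DLA value: fitting $N \propto R_g^D$ across cluster sizes 750-12000
gives $D \approx 2.5{-}2.6$, and the pair-distance distribution of a
24000-monomer cluster scales as $r^{D-1}$ with $D \approx 2.40{-}2.47$
over more than a decade.

The *scattering* readout is systematically shallower. The Porod-window
slope of `cluster_curve()` (sphere form factor times the coherent
interference term) fitted between the Guinier and monomer scales reads
about $-2.1$ to $-2.35$ for single clusters of $3\times10^3$ to
$10^5$ monomers, for seed-averaged curves, and for polydisperse
ensembles. The package treats this as a real property of finite
aggregates, not an estimator defect, on the strength of a controlled
experiment: sinc-transforming an ideal $p(r) = r^{1.45}$ with a sharp
cutoff reproduces the shallow reading ($\approx -1.9$ in the same
window), while the same power law with a smooth tail reads
$-2.43$ to $-2.50$. The hard density cutoff at a finite cluster's
envelope leaks into the fractal window of the transform. Experimental
debris samples — polydisperse, orientationally averaged, and with
instrument smearing — approach the ideal smooth-cutoff limit more
closely than any single simulated cluster can. Analyses that need the
asymptotic dimension should therefore use the mass-radius or
pair-distance routes; the scattering-window slope underestimates $|D|$
by roughly 0.2-0.3 at these sizes.

## 10. Limitations

* Class-level biomass formulas are stoichiometric averages; residue-level
  deuteration patterns, lipid headgroup diversity and bound ions are not
  modelled.
* The hydration shell is a uniform-density layer; real shells are
  anisotropic and exchange-broadened.
* Instrument resolution smearing (wavelength spread, collimation) is not
  modelled; simulated peaks are sharper than measured ones.
* The bead-model search space is a fixed lattice inside a sphere;
  strongly elongated particles need `search_diameter` set generously and
  more annealing steps.
* Finite-cluster fractal slopes are shallower than the asymptotic
  dimension (section 9).
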