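---
title: "Model and methods behind oncosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind oncosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

oncosim is a cell-level, off-lattice simulator of the earliest phase of
tumor formation: a small disc (2D) or ball (3D) of epithelial tissue in
which dividing cells occasionally mutate into fast-cycling tumor cells,
tumor cells secrete a chemokine that recruits T-cells out of nearby blood
vessels, T-cells chase and engulf tumor cells, and tumor cells that press
hard against a vessel wall intravasate and may seed distant sites. This
vignette describes the model, its numerical treatment, the parameters that
matter, and the design choices we made where the model as published leaves
the design open.

## The model

**Cells.** Each cell is a sphere (circle in 2D) with a phenotype
(epithelial, tumor, T-cell), a position, a radius in
$[R_0, R_{\max}]$ with $R_{\max} = 2^{1/3} R_0$, a cycle phase and phase
age, and a traction force $F$. The state is a tidy table (one row per
cell), so everything composes with ordinary data-frame tooling.

**Chemokine transport (mesh-free).** Tumor cells are moving point sources
of a chemokine with constant secretion rate $\gamma$ diffusing with
diffusivity $D$. Instead of discretizing the domain, the concentration at a
point $x$ and time $t$ is the Duhamel superposition of free-space heat
kernels over each source's recorded trajectory
$x_j(s)$:
$$c(t,x) = \sum_j \int_{\tau_B^j}^{\min(t,\tau_D^j)}
\frac{\gamma\, \exp\!\big(-\lVert x - x_j(s)\rVert^2 / 4D(t-s)\big)}
     {\big(4\pi D (t-s)\big)^{d/2}} \, ds .$$
Traces of dead cells are retained: their chemokine keeps dispersing after
the cell is gone. Gradients are the analytic spatial derivatives of the
same integrals. The integrals are evaluated with the trapezoidal rule on
the recorded samples (cadence `dt_quad`, default 5 s), with two published
economies: contributions of a dead source are dropped once
$t - \tau_D \ge \tilde t$ (default 80 s), and history older than
$t - t^*$ (default 80 s) is replaced by a closed-form tail in which the
spatial factor is dropped. The 2D tail is exact under that approximation;
the 3D tail is the published coarse (upper-bound-style) form, which is
dimensionally looser — the package keeps it as published, and the shipped
experiments are 2D, where the form is consistent. Because the spatial
factor with the default $t^*$ satisfies
$r^2/(4 D t^*) \le 0.05$ across a default-size domain, the dropped
exponential is $\ge 0.95$.

**Mechanics.** A cell pulling with force $F$ on a substrate of stiffness
$E_s$ stores the strain energy density $M^0 = F^2 / (2\pi^2 E_s R^4)$,
sensed by other cells attenuated as $\exp(-\lambda \lVert x - x_j\rVert /
R_j)$ and cut off beyond $L = 30\,\mu m$. Overlapping cells repel via
Hertz contact energies $\propto E_c (h/R)^{5/2}$ with penetration depth
$h$; the domain wall acts as a mirror cell and vessels as spheres of
radius $R_b$. Remote terms attract (mechanotaxis), contact terms repel;
the resultant direction $\hat z_i$ and the total sensed energy $M(x_i)$
drive the deterministic drift $\alpha_i M(x_i) \hat z_i$ with mobility
$\alpha_i = (F_i/\hat F)^2 \beta R^3 / f$. T-cells additionally drift up
the chemokine gradient with sensitivity $\mu = 10^4\,\alpha_i$
($5 \times 10^4$ in the "good immune" configuration). All cells undergo a
random walk $\sigma\,dW$; cells in mitosis move only by contact forces.

**Cycle, death, immunity.** G1, G2 and M have fixed durations; the S phase
is exited each step with probability $(\Delta t / T_S) F(p)$, where
$F(p) = c_1/(1 + c_2 e^{c_3 p})$ and $p$ is the summed contact energy the
cell endures, so S residence is geometric with mean $T_S/F(p)$ and
crowding slows proliferation. Death is calibrated against the observed
colony doubling time $T_2$: per step, $P_D = 1 - 2^{(1/T_2 - 1/T_C)\Delta
t\, G}$. Division replaces the mother by two daughters of radius $R_0$
touching at the mother's center along a uniformly random direction;
epithelial daughters mutate to the tumor phenotype with probability $P_M =
0.25$. T-cells extravasate at vessel points with per-second probability
$A c^2/(B + c^2)$, engulf tumor cells instantly on contact, and die by the
same death law (epithelial calibration). A tumor cell in contact with a
vessel sphere whose sensed energy exceeds $M_b^* = 0.1$ kPa intravasates;
each intravasation seeds with probability $P_S$.

**Time integration.** The deterministic drift is integrated with classical
RK4 (the chemokine gradient and the noise are frozen within substeps); the
random walk uses the Euler–Maruyama increment $\sigma \sqrt{\Delta t} Z$.
The step size adapts so that no cell is predicted to move more than a
quarter of its diameter ($R/2$), including a $3\sigma$ noise allowance; a
step that still overshoots is redone at half the step, and at the floor
`dt_min` the offending displacement is clamped (counted in the run's
diagnostics).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| $D$ | 100 | $\mu m^2/s$ | chemokine diffusivity |
| $\gamma$ | 2 | conc./s | secretion per tumor cell |
| $E_s$, $E_c$ | 5, 0.5 | kPa | substrate / cell stiffness |
| $L$ | 30 | $\mu m$ | mechanical sensing cutoff |
| $R_0$, $R_{T}$ | 3, 4.5 | $\mu m$ | cell and T-cell radii |
| $T_{G1},T_S,T_{G2},T_M$ | 300/400/300/1 (epith.), 10/0/10/1 (tumor) | s | phase means |
| $T_2$ | $10^7$ (epith.), 4000 (tumor) | s | doubling-time calibration |
| $P_M$ | 0.25 | – | mutation per division |
| $A$, $B$ | 0.05, 200 | –, conc.$^2$ | extravasation response |
| $c_1..c_5$ | 11, 9, 1, 9, 10 | – | pressure responses |

The cycle times are deliberately compressed (the tumor cycle of 21 s is a
dimensionless exaggeration to make tumor turnover visible on simulation
timescales), so absolute times should be read comparatively, not as
biological seconds.

## Design choices

Where the published model leaves a constant or a rule open, the package
fixes it once and exposes it in the configuration:

* **Attenuation $\lambda$** has no published value; the default is 10,
  which confines a cell's mechanical signal to a few radii. Because of
  this, legitimate remote signals are numerically tiny; the migration
  direction is therefore declared absent only when the resultant is
  exactly zero (perfect symmetry), never by a magnitude threshold.
* **Noise magnitudes** $\sigma = 0.1\ \mu m\,s^{-1/2}$ and $\sigma_g =
  0.01\ \mu m\,s^{-1/2}$ are defaults chosen to keep the random walk a
  fraction of a radius per step; both can be set to 0 for deterministic
  runs.
* **Normalized pressure-death response.** As printed, the death factor
  $G(p) = c_4/(1+e^{-c_5 p})$ equals 4.5 at zero pressure, which
  contradicts the calibration that derives $P_D$ from the doubling time
  $T_2$ (an unloaded colony would die $4.5\times$ faster than its own
  calibration and every phenotype would have negative net growth; no tumor
  could ever expand). `death_prob()` implements the published formula
  exactly, and the engine's default applies $G(p)/G(0)$ — the published
  shape, renormalized so that zero pressure recovers the $T_2$
  calibration and crowding raises death by up to $2\times$. The raw and
  pressure-free variants remain available via `engine$death_response`.
* **Active-drift speed cap `v_max`** (default 1 $\mu m/s$). The
  phenomenological mobility gives $\alpha \approx 1.35 \times 10^3\ \mu
  m\,kPa^{-1} s^{-1}$ and $\mu = 10^4 \alpha$, so any appreciable
  chemokine gradient implies drift speeds of $10^5\,\mu m/s$ and the
  quarter-diameter rule would drive the step size toward zero. Real
  leukocytes migrate at fractions of a micron per second; capping the
  active drift keeps speeds in that regime while preserving direction.
* **Initial packing 0.72.** The tissue is initialized by random sequential
  placement plus contact-relaxation sweeps (radii grown in stages) until
  the largest overlap is below $10^{-3} R_0$; random disc packings jam
  near coverage 0.82, so the default coverage 0.72 (about 128 cells in
  the 40 $\mu m$ disc) is confluent yet reliably relaxable. Cells start in
  G1 with uniformly random phase ages, avoiding artificial division waves
  (`engine$synchronized_start` restores synchrony).
* **Doubling-time measurement.** The branching-colony doubling time is
  measured from the stationary age profile $\rho(a) \propto 2^{-a/T_C}$ of
  a steadily growing colony, which is the regime the calibration
  describes. A synchronized start makes the colony divide in waves (the
  population sawtooths by $2\times$ within every cycle) and biases the
  first-passage time upward by roughly 15%. Even in the stationary
  regime the estimator retains a mild (about $-6\%$) first-passage skew:
  upward fluctuations are absorbed at the target while downward ones
  persist. The reported value is the honest mean of that estimator.
* **T-cell death** reuses the death law with the epithelial calibration,
  the minimal reading of "death of a T-cell is described by a stochastic
  variable" with no published constants.
* **Vessels** are represented by their boundary points with contact
  spheres of radius $R_b$; intravasation requires both vessel contact and
  the energy criterion, since the energy criterion alone carries no
  locality.

## What the generator emulates — and what it does not

The built-in initializer produces the study tissue: a 40 $\mu m$ disc
(ball) of desynchronized epithelial cells with 4 (2D) or 6 (3D) vessel
points on the boundary, optionally with a central micro-tumor
(`engine$initial_tumor`) standing in for the mutation-driven emergence
that otherwise takes several hundred seconds of epithelial cycling. It
does not emulate: real tissue architecture or heterogeneity, anisotropic
or spatially varying stiffness and diffusivity (explicitly out of the
model), nutrient fields, vascular flow, or bounded-domain diffusion (the
fundamental solutions live on free space). Passing tests therefore
demonstrate internal correctness of the stated model, not predictive
accuracy for real tissue.

A known quantitative limitation: with the published constants in the
fixed internal unit system ($\mu m$, s), the chemokine concentration at
the vessel points stays orders of magnitude below $\sqrt{B}$ (a
micrometer-scale source cluster with $D = 100\ \mu m^2/s$ dilutes to
$c \sim 10^{-2}$), so extravasation is extremely rare and the simulated
immune response is much weaker than the published qualitative figures
suggest; those figures imply an internal concentration scale that is never
stated (the published chemokine units are themselves inconsistent between
the transport equation and the parameter table). We keep the published
values rather than inventing a rescaling, and the immune-comparison
experiment reports whatever contrast they actually produce.

## Numerical choices and problem sizes

Quadrature uses the trapezoidal rule on non-uniform nodes; the most recent
node is the last recorded sample (no evaluation at $s = t$, where the
integrand is an indeterminate 0 for $r > 0$); evaluations closer than
`eps_r` (0.5 $\mu m$) to a source sample are clamped with a warning.
Radius growth carries cells from $R_0$ to $(R_0 + R_{\max})/2$ during G1
and onward to $R_{\max}$ during G2 ($\kappa = (R_{\max}-R_0)/(T_{G1} +
T_{G2})$), clamped to $[R_0, R_{\max}]$. Ties and degeneracies: a
phenotype with $T_S = 0$ skips S entirely; division directions are drawn
uniformly on the sphere; coincident cell centers are a contract violation
(prevented by repulsion plus the displacement cap).

The shipped test suite and experiments use deliberately modest problem
sizes chosen as representative rather than exhaustive: the standard
40 $\mu m$ disc (about 128 cells), short horizons (tens to hundreds of
seconds), 10 paired replicates for the immune comparison, and 20–200
replicates of the 2000-cell branching colony for the doubling-time
calibration. All randomness is seeded; identical configuration and seed
reproduce runs bit-for-bit.
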