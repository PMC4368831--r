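---
title: "Quasi-potential energy landscapes for a three-node yeast cell-cycle network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-potential energy landscapes for a three-node yeast cell-cycle network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The package studies a deliberately reduced picture of the budding yeast cell
cycle: three modules — G1/S (variable $x$), early M ($y$) and late M ($z$) —
each with a second-order Hill positive feedback, linear degradation, a
bilinear repression from the downstream module, and a trigger input from the
upstream one:

$$
\begin{aligned}
\dot x &= \frac{x^2}{j_1^2 + x^2} - k_1 x - x y + a_0,\\
\dot y &= \frac{y^2}{j_2^2 + y^2} - k_2 y - y z + k_{a1}\, x,\\
\dot z &= k_s \frac{z^2}{j_3^2 + z^2} - k_3 z - k_i\, z x + k_{a2}\, y.
\end{aligned}
$$

The defaults (`cc_params()`) are $j_{1,2,3} = 0.5$, $k_{1,2,3} = 0.2$,
$k_i = 5$, $k_s = 1$, $k_{a1} = k_{a2} = 0.001$ and $a_0 = 0.001$; all
quantities are in dimensionless concentration/time units.  $a_0$ encodes
nutrient availability, the $k_a$ rates the strength of the DNA-replication
and mitosis triggers.  At the defaults the system is *excitable*: a stable
G1 state P1 $\approx (0.006,\,10^{-6},\,4.325)$ coexists with a saddle P2
$\approx (0.045,\,0,\,2.248)$; a perturbation past the saddle launches one
full excursion — up the S-phase leg to the vertex P3, across the S/M
transition, up the early-M leg to P4, and back to G1 — before the system
settles again.  G2 is not modelled, and there is no cell-mass variable: the
excursion is a "domino" cascade triggered entirely by the network itself.

Two numerically relevant details are worth recording.  First, the strict
model is weakly bistable: the $a_0$ term creates a second stable point with
a tiny basin next to the origin ($\approx (0.006, 3\times10^{-5}, 10^{-7})$).
It plays no role in the cycle and all landscapes here are local
quasi-potentials relative to P1.  Second, the "vertices" P3 $=(x_{\max},0,0)$
and P4 $=(0,y_{\max},0)$ are *not* fixed points of the full system.  We
define $x_{\max}$ and $y_{\max}$ as the peak values of $x$ and $y$ along the
deterministic excursion (`cc_vertices()`), not as the roots of the decoupled
one-variable subsystems: the trigger terms make the excursion turn around
before reaching those roots (at baseline $x_{\max}\approx 4.31$ versus a
subsystem root of $4.95$), and the same coupling is what shifts the G1 state
to $z \approx 4.32$ rather than the uncoupled root $4.95$.  Under the weak
S-checkpoint trigger ($k_{a1} = 10^{-4}$) the excursion climbs to
$x_{\max} \approx 4.89$, so each parameter set carries its own vertices.

## Noise models and the quasi-potential

Intrinsic noise is modelled by translating each additive term of the
equations into a reaction channel at system size $V$: twelve channels, with
the $x$-equation propensities $a_1 = VX^2/((j_1V)^2 + X^2)$, $a_2 = k_1X$,
$a_3 = XY/V$, $a_4 = a_0V$ and the $y$/$z$ equations treated by exact
analogy (`cc_network()`).  With this $O(V)$ scaling the mean-field identity
$\sum_j \nu_j a_j(Vx)/V = b(x)$ holds *exactly* at every finite $V$ — an
algebraic property the tests exploit — and $X(t)/V$ converges to the
deterministic flow as $V \to \infty$.  Extrinsic noise is additive white
noise of magnitude independent of the network, $\dot x = b(x) +
\epsilon\dot w$.

Both noise models define a large-deviation Hamiltonian with $H(x, 0) = 0$
and convex momentum dependence:

* intrinsic: $H(x,p) = \sum_j a_j(x)\,(e^{p\cdot\nu_j} - 1)$,
* extrinsic: $H(x,p) = p \cdot b(x) + |p|^2/2$.

The local quasi-potential $S(x; x_0)$ is the infimum of the path action over
all connecting paths and durations; it satisfies the Hamilton–Jacobi
equation $H(x, \nabla S) = 0$, decays along deterministic trajectories
(Lyapunov property), sets exit times through $\tau \propto e^{V\Delta S}$,
and reduces to $2U$ for a gradient system $\dot x = -\nabla U +
\epsilon\dot w$ — the calibration case used throughout the test suite.

## Geometric action numerics

The action is minimized in its time-free (Maupertuis) form.  For a chord
$v$ at midpoint $x$ the local cost is the support function of the zero
sublevel set of $H$:

$$\ell(x, v) = \sup\{\,p\cdot v : H(x,p) \le 0\,\}
            = \inf_{\tau>0}\ \tau\, L(x, v/\tau).$$

This form has three properties the implementation leans on.  It is
1-homogeneous in $v$, so the discrete action is invariant under
reparametrization of the curve.  It vanishes exactly when $v$ is aligned
with the drift (relaxation is free).  And for the jump Hamiltonian it is
*separable*: with per-coordinate birth/death sums $B_k, D_k$ the inner
conjugate maximization is closed-form per coordinate
($e^{p_k^*} = (w_k + \sqrt{w_k^2 + 4B_kD_k})/2B_k$), leaving a single scalar
Maupertuis condition $H(x, p^*(v/\tau)) = 0$, monotone in $\tau$, solved by
safeguarded Illinois iteration with warm starts.  For the extrinsic kind the
cost is fully closed-form, $\ell = |b||v| - b\cdot v$.  Momenta are clipped
at $\pm 35$ per component so the exponentials stay finite on the boundary
faces where channels die out ($y = 0$ with $x = 0$ kills the $y$-birth sum);
directions that are strictly impossible (moving against an extinct channel)
price at the clip value, which repels paths from them.

Paths are relaxed by projected Barzilai–Borwein gradient descent (analytic
gradients via the envelope theorem), interleaved with arc-length
reparametrization; endpoints are pinned, coordinates floored at zero for
concentration models.  Landscape grids are filled outward from the
attractor with two accelerations: each node is warm-started from its best
converged grid neighbour, and optionally from a *skeleton* — the
deterministic excursion path prepended with the P1→P2 segment
(`cc_skeleton()`) — which lets the minimizer discover the canal route
instead of tunnelling straight through high-action territory.  After the
fill, improvement sweeps let every node retry seeds morphed from all its
neighbours and keep the best relaxed result; two to three sweeps remove
essentially all route inconsistency between neighbouring nodes (the
dominant noise source in the raw fill).  Nodes whose solves fail are
recorded as missing, never extrapolated.  For a limit-cycle attractor
(rich-nutrient regime) the zero level set is the stored cycle and each path
starts from its nearest cycle sample.

Defaults: grids of $21^3$ nodes for tests and $61^3$ (or $61^2$ planar
slices) for production figures over $[0,6]$ per axis; 16 path nodes per
grid target and 100 for single transitions; relative action tolerance
$10^{-6}$ per node.  Single-path studies (barrier heights, the calibration
cases) use more nodes and iterations, e.g. `g1_well_depth()`.

### The Hamilton–Jacobi residual

`hj_residual()` reports $|H(x, \nabla S)|$ with central finite-difference
gradients over interior defined nodes — a self-consistency diagnostic, not
a solver.  Two facts shape how we use it.  On analytically known
landscapes (the 1-D birth–death system) the residual converges to zero
with spacing, and that is asserted in the tests.  On the 3-D cell-cycle
grids the *intrinsic* residual is exponentially sensitive to momentum
error ($\partial H/\partial p \sim e^{|p|}$, with $|\nabla S|$ reaching
5–10 in the high-$S$ outskirts), so once finite-difference error is
dominated by per-node solver noise rather than truncation, its mean no
longer falls under grid refinement even while the $S$-field itself
demonstrably converges (the median neighbour-Laplacian of $S$ drops
roughly in proportion to the spacing).  The refinement check in the
acceptance suite therefore uses the extrinsic baseline landscape — whose
residual amplifies momentum error only linearly — with the curve
discretization refined together with the grid ($21^3$/24 path nodes
against $41^3$/48), where the decrease is clean and costs under two
minutes.  The intrinsic 3-D residual remains available and is reported as
run metadata.

## Non-gradient force and the pseudo landscape

Along the excursion the landscape is nearly flat — a "canal" — so $S$ alone
cannot show the direction of motion.  The most probable cycling path obeys
$\dot x = \nabla_p H(x, \nabla S) = F(x)$; where $\nabla S = 0$ this reduces
exactly to $F = b$ (for the extrinsic kind, $F = b + \nabla S$).
`force_field()` evaluates $F$ on a grid; the acceptance suite additionally
evaluates $\nabla S$ at canal points by symmetric differencing of direct
minimum-action solves, which avoids grid error entirely.

The *pseudo landscape* (`build_pseudo()`) makes the drive visible: remove
the G1 well from view and encode the force tangentially.  Its two defining
properties are that the tangential steepness equals the driving-force
strength and that the transverse profile is unchanged.  We realize them
minimally: $T(s) = -\int_0^s \|b(\phi(u))\|\,du$ along the arc-length
parametrized canal (so $|dT/ds| = \|b\|$ by construction, steep at the fast
mid-canal stretches and almost flat near the slow vertices), plus the local
quasi-potential in the plane normal to the path at each section, with the
path point as origin.  The combined value near the path is $T(s^*) +
S_\perp$ with $s^*$ the nearest path point (ties broken toward smaller
$s$).  Any construction with the same two properties could be swapped in;
this one is isolated behind a single function on purpose.  The pseudo
landscape is local by design and does not represent the stationary
distribution.

`canal_width_profile()` quantifies confinement: the transverse distance at
which the global quasi-potential rises by a fixed offset (default 0.01,
the finite-volume scale at $V = 100$) above the canal floor, averaged over
both sides.  Two implementation notes matter here.  First, the width must
be read off the *global* landscape $S(\cdot; P_1)$: the local action from a
moving path point is linear in the displacement with slope of order
$\|b\|$ (the support function of a level set not centred at the origin),
which would make any "width" scale like the inverse force — an artifact of
the origin choice, not the confinement the landscape shows.  Second, the
transverse direction is taken within the coordinate plane the canal
currently hugs.  Under intrinsic noise the measured canal is substantially
narrower near the slow vertices P3 and P4 than along the fast mid-canal
stretches (at baseline roughly 0.04 and 0.013 against 0.09), the
landscape's footprint of the fact that the jump-noise intensity follows
the reaction rates, which nearly vanish where the cycle stalls; the
property tests assert this ordinal structure together with the
two-orders-of-magnitude collapse of the transverse noise intensity itself.
We deliberately do not assert a blanket comparison of width *variability*
between the intrinsic and extrinsic landscapes: in this model the
transverse contraction rate varies by a factor of about 65 along the
cycle and dominates both profiles, while the intrinsic intensity co-varies
with it and partially cancels, so fixed-offset widths vary at least as
much under extrinsic as under intrinsic noise whichever way the offsets
are scaled.  Simulated trajectory spreads (`em_simulate()` +
`canal_transverse_spread()`) are additionally blurred by non-adiabatic
memory: a fast station inherits the spread acquired in the slow region
just upstream.

## Finite-volume landscapes from simulation

`ssa_simulate()` is an exact Gillespie direct-method simulator of the
12-channel network (the package's synthetic-data generator), bitwise
reproducible given a seed.  `stationary_histogram()` accumulates
residence-time-weighted occupancy over concentration bins (default
$60^3$ over $[0,6]$), and `finite_volume_landscape()` defines the sampled
landscape as $-\ln \hat P$, with empty bins marked missing and per-bin
standard errors attached when the run is split into independent replicate
chunks.

Because the excitable baseline funnels into G1 and re-excites only on
astronomically long timescales, cycle statistics are collected by
*conditioning*: whenever the walker enters a ball (radius 1.0) around P1 it
is reinjected at the excited-G1 point just past P2, and residence inside
the ball is not scored.  The result is a conditioned cycling distribution —
deliberately not the global stationary law — matching how the cycling-path
statistics must be read.  At $V = 100$ (small enough that reaction rates
near the vertices are comparable to the noise, large enough that the canal
is recognizable) the $-\ln \hat P$ surface develops pits on the $z=0$ and
$x=0$ slices within a short distance of P3 and P4: the slow-passage regions
act as extra checkpoints.  The infinite-volume quasi-potential slices have
no minima there — the pits are a pure finite-volume effect.  Pit detection
uses the replicate standard errors: a bin counts as a pit only when it lies
below every defined neighbour by more than twice the combined standard
error, which suppresses both shot noise and the binning ripples along the
canal floor.

Exit times: `mean_exit_time()` samples first-passage times with
per-replicate seeds derived from a master seed; `bd1_exact_mfpt()` provides
the closed-form chain solution used as the oracle.  For the
$\tau \propto e^{V\Delta S}$ law the tests simulate the 1-D birth–death
system over $V \in \{40, 60, 80, 100\}$ (100 replicates each, exit at
$x = 1.5$ from the well at $x = 1$, $\Delta S = 1.5\ln 1.5 - 0.5 \approx
0.108$).  The plain $\ln\bar\tau$–$V$ regression is linear to $R^2 >
0.999$, but its slope is biased low by the slowly varying subexponential
prefactor (about $0.55/\bar V$, i.e. 6–14% at desk-scale volumes — the
exact chain solution shows the same bias, so it is a property of the law at
finite $V$, not of the sampler).  The slope compared against $\Delta S$ is
therefore taken from the prefactor-corrected fit $\ln\bar\tau = a + b\ln V
+ sV$, whose bias at these volumes is below 1%; its bootstrap CI is the
acceptance interval.

## Scenario presets

`cc_scenario()` wires the signal-response experiments: `baseline`
(excitable, stable G1 global minimum, flat canal), `rich_nutrient`
($a_0 = 0.01$: the G1 state vanishes in a saddle-node at $a_0^* \approx
0.0025$ — located by `locate_bifurcation_a0()` via bisection on the
existence of a stable G1-like fixed point ($z > 1$, $x, y < 0.5$) — leaving
a stable limit cycle), `s_checkpoint` ($k_{a1} = 10^{-4}$) and
`m_checkpoint` ($k_{a2} = 10^{-4}$).  The weak trigger of a checkpoint
creates a genuinely stable fixed point near the corresponding vertex
(at $(4.89, 0.0026, 0)$ for the S checkpoint), so the canal floor acquires
a pit that holds the system until the parameter is restored — the landscape
realization of checkpoint arrest.  `run_scenario()` executes a requested
analysis plan and checks the expected features; `compare_scenarios()`
diffs regimes, stable states and slice pits.  Checkpoint pits are "near"
their vertex within a ball of radius 0.5 in concentration units.

## What the tests do and do not show

All empirical statements in the test suite are made against the synthetic
generator and analytic oracles: closed-form 1-D birth–death actions and
mean first-passage times, the $S = 2U$ gradient calibration, the exact
mean-field identity, and the qualitative landscape topology the model
produces.  The generator emulates intrinsic reaction noise of the reduced
three-node network at a single volume; it does not emulate transcriptional
bursting, cell-to-cell parameter variability, growth/division asymmetry or
the dozens of regulators absorbed into each module.  Passing tests
therefore validate the machinery and the model's landscape structure, not
quantitative predictions about living yeast.

Problem sizes used by the test suite (package choices, reported for
reproducibility): intrinsic $21^3$ grid over $[0,5]^3$ for the Lyapunov and
canal-flatness checks; extrinsic $21^3$/$41^3$ refinement pair; $61^2$
checkpoint slice; $6\times10^5$ time units of conditioned SSA at $V = 100$
in four replicate chunks; 100 exit-time replicates per volume.

## Known limitations

* Grid fills in the far high-$S$ region of the intrinsic landscape carry
  route noise of order a few percent of $S$; conclusions there should use
  direct `quasipotential_at()` solves rather than grid interpolation.
* `glue_global()` implements the sticking construction for one or two
  attractors (offsets from the pairwise transition costs); more attractors
  would need the full hierarchy of exit costs.
* The gMAM relaxation is first-order; paths through strongly curved
  boundary regions converge slowly and are capped by `max_iter`
  (unconverged nodes are flagged, and improvement sweeps usually repair
  them).
* Exact SSA only — no tau-leaping — so volumes much beyond $V \sim 2000$
  become expensive.
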