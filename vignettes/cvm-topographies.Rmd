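---
title: "Characterizing binary grid topographies with the 2-D cluster variation method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing binary grid topographies with the 2-D cluster variation method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvm2d)
```

## The model

The cluster variation method (CVM) is a hierarchy of entropy approximations
for lattice systems: instead of writing the entropy over single-site
occupation probabilities alone, it writes it over the probabilities of
small local clusters. `cvm2d` implements the two-dimensional member of that
hierarchy whose clusters are single units, nearest-neighbor pairs,
next-nearest-neighbor pairs, and three-unit triplets, on a grid of bistate
units (state A = "on" = 1, state B = "off" = 0).

The lattice is a stack of overlapping zigzag chains: each row is offset
from its neighbors by half a unit, and both directions wrap around
(a torus). Under this geometry a unit's four *nearest* neighbors lie in the
rows immediately above and below it, its four *next-nearest* neighbors lie
in its own row (left and right) and two rows above and below, and triplets
are read as length-3 windows along the two-row zigzag chains. In this
package even-indexed rows (0-based) are the ones displaced half a cell to
the right; any consistent choice of offset is equivalent up to relabeling,
but one must be fixed for bit-exact testing. The row count must be even so
that the vertical wrap joins rows of opposite offset parity.

A grid's local pattern statistics are summarized by the **configuration
variables**:

* $x_1, x_2$ — fractions of units in states A and B;
* $y_1, y_2, y_3$ — fractions of nearest-neighbor pairs that are A–A,
  A–B (either orientation), and B–B;
* $w_1, w_2, w_3$ — the same for next-nearest-neighbor pairs;
* $z_1 \dots z_6$ — fractions of triplet windows that read A-A-A, A-A-B
  (pooled with B-A-A), A-B-A, B-A-B, B-B-A (pooled with A-B-B), and B-B-B.

The mixed classes can be realized in two orientations, which gives them
degeneracy factors $\beta_2 = 2$ (pairs) and $\gamma_2 = \gamma_5 = 2$
(triplets); all other degeneracies are 1. `cvm2d` stores the degenerate
classes as *per-orientation* fractions, so the normalizations are

$$x_1 + x_2 = 1,\qquad
  y_1 + 2y_2 + y_3 = 1,\qquad
  w_1 + 2w_2 + w_3 = 1,$$
$$z_1 + 2z_2 + z_3 + z_4 + 2z_5 + z_6 = 1.$$

On a toroidal grid of $N$ units there are exactly $2N$ nearest-neighbor
edges, $2N$ next-nearest windows ($N$ same-row and $N$ two-rows-down), and
$2N$ triplet windows, so the counted fractions satisfy these identities
identically — the tallies are exact integers, and the normalized fractions
carry at most one floating-point ulp of error. They also satisfy the
equivalence relations

$$y_2 = z_2 + z_4 = z_3 + z_5,\qquad y_1 = z_1 + z_2,\qquad
  y_3 = z_5 + z_6,$$

structurally: every nearest-neighbor edge appears exactly twice as a
middle–end incidence of a triplet window, once seen from each endpoint.
`check_equivalences()` exposes the four residuals, and the test suite
verifies they vanish for every counted grid.

### Horizontal-window triplet counting

Triplets are counted along the two-row zigzag chains only ("horizontal"
windows). Windows that would extend two rows up or down are not part of
this scheme. Counted this way, every site is the middle of exactly two
windows — one whose ends are its two up-neighbors, one whose ends are its
two down-neighbors — which is what makes the census ($\sum_i \gamma_i Z_i =
2N$) and the equivalence relations exact. The package implements no other
triplet mode.

### Thermodynamics

With $k_\beta T = 1$, the reduced (per-unit) free energy of a
configuration-variable state is $\bar F = \bar H - \bar S$ with

$$\bar H = \varepsilon_0 x_1 +
  \varepsilon_1 (z_3 + z_4 - z_1 - z_6),$$

where $\varepsilon_0$ is the *activation enthalpy* (energy carried by each
"on" unit) and $\varepsilon_1$ the *interaction enthalpy* (penalty for
unlike nearest neighbors, reward for like ones). By the equivalence
relations the interaction term equals
$\varepsilon_1(2y_2 - y_1 - y_3)$ on any counted grid. A `"legacy"` variant
$\varepsilon_1 \cdot 2y_2$, used by earlier implementations and differing
only in the scaling of the interaction term, is available behind a flag.

The CVM entropy is

$$\bar S = 2\sum_{i=1}^{3}\beta_i\,\mathrm{Lf}(y_i)
  + \sum_{i=1}^{3}\beta_i\,\mathrm{Lf}(w_i)
  - \sum_{i=1}^{2}\mathrm{Lf}(x_i)
  - 2\sum_{i=1}^{6}\gamma_i\,\mathrm{Lf}(z_i),
  \qquad \mathrm{Lf}(v) = v\ln v - v.$$

It is 0 for a homogeneous grid and $\ln 2$ at the equiprobable random
point. No Lagrange-multiplier terms appear in $\bar F$: grid-derived
fractions satisfy the normalization and consistency constraints
identically, so those terms would contribute zero.

### The analytic equilibrium in $h$

For $\varepsilon_0 = 0$ the equilibrium is equiprobable
($x_1 = x_2 = 0.5$) and has a closed form, naturally expressed in the
substitution parameter $h = e^{2\varepsilon_1}$:

$$\Delta = -h^2 + 6h - 1,\qquad
  y_1 = y_3 = \frac{3h-1}{2\Delta},\qquad
  y_2 = \frac{h(3-h)}{2\Delta},$$
$$w_1 = w_3 = \frac{(h+1)^2}{4\Delta},\qquad
  w_2 = \frac{(3h-1)(3-h)}{4\Delta},$$
$$z_1 = z_6 = \frac{(3h-1)(h+1)}{8\Delta},\qquad
  z_2 = z_5 = \frac{(3h-1)(3-h)}{8\Delta},\qquad
  z_3 = z_4 = \frac{(3-h)(h+1)}{8\Delta}.$$

This is the unique reading of the closed form that simultaneously
satisfies the three normalization identities, the equivalence relations,
and a common denominator $\Delta$ — the package's tests verify all three
numerically over a grid of $h$ values. The solution diverges at the roots
of $\Delta$, $h = 3 \mp 2\sqrt 2 \approx 0.172$ and $5.828$
(equivalently $\varepsilon_1 \approx 0.8814$ at the upper root);
`analytic_equilibrium()` refuses evaluation within $10^{-6}$ of either
root rather than return huge magnitudes, and the valid interval is open.
Note that for $h > 3$ some closed-form fractions are negative: the
stationary point leaves the physically realizable region well before the
divergence.

```{r analytic}
divergence_points()
analytic_equilibrium(1.65)
```

When instead the *interaction* enthalpy is zero, units are independent and
the minimizing single-unit fraction is logistic,
$x_1 = 1/(1 + e^{\varepsilon_0})$, with every pair and triplet fraction an
independence product ($y_1 = x_1^2$, $z_1 = x_1^3$, ...). That formula is
not taken on faith: a test minimizes the implemented free energy
numerically over independence-product states and confirms the minimizer.

### Interpretation variables

Three configuration variables suffice to summarize a topography: $z_1$
(A-A-A triplets — interior mass), $z_3$ (A-B-A triplets — jagged borders),
and $y_2$ (unlike pairs — boundary dispersion). `cvm2d` reports $y_2$ in
the per-orientation (halved) convention everywhere user-facing; the raw
unlike tallies remain available in `cvm_counts`. Published tabulations of
such quantities do not always state whether degeneracy-summed ($2y_2$) or
per-orientation values are meant, and the two differ by a factor of two;
fixing the per-orientation convention package-wide (it is the one under
which the normalization identities read as above) avoids that ambiguity.

## Free-energy minimization

`minimize_free_energy()` drives a grid toward a free-energy minimum by the
simplest conserved-magnetization dynamics: repeatedly pick one random A
unit and one random B unit, swap them, recount, and keep the swap if and
only if $\bar F$ strictly decreased. Ties are rejected, which keeps traces
strictly monotone. The A-count (hence $x_1$) is conserved exactly. $h$ is
held fixed during a run: raising $h$ always lowers the enthalpy, so a free
$h$ would be driven upward instead of reshaping the topography.

Termination, in order of precedence: `max_accepted_swaps` accepted swaps
(default 100 — a swap "budget" read as *accepted* swaps, with a separate
`max_attempts` cap of 10,000 proposals preventing livelock);
`stall_attempts` consecutive proposals (default 500) without an
improvement exceeding `f_tolerance` (default 0), reported as `converged`;
or the attempt cap. Every proposal recomputes the free energy from a full
vectorized recount (about 0.3 ms at 16 × 16); at the grid sizes this
package targets an incremental-update path would add complexity without a
measurable benefit, so there is deliberately only one code path.

`perturb()` applies unconditional swaps to jostle a converged grid, and
`sweep_h()` chains generation, minimization, and optional
perturb/re-minimize cycles (default 0 cycles) over a vector of $h$ values.

A structural consequence worth knowing when reading sweep output: the
minimized-state interaction enthalpy $\bar H$ is identically 0 at $h = 1$
(there $\varepsilon_1 = 0$, so the interaction term vanishes for *any*
state) and strictly negative on both sides — at the analytic equilibrium
$\bar H = -\varepsilon_1 (h+1)(h-1)/\Delta$, which is $\le 0$ with
equality only at $h = 1$. Mean minimized $\bar H$ over a sweep therefore
*rises* toward zero as $h \to 1$ from below (the antiferromagnetic side)
and falls with $h$ on the ferromagnetic side $h \ge 1$; it is not monotone
across $h = 1$. On the $h \ge 1$ branch, the enthalpy term increasingly
dominates the entropy as $h$ grows.

## Topography generators

Three generators produce the study's initial conditions, all with an exact
A-count (default $x_1 = 0.5$, i.e. 128 A-units at 16 × 16):

* `generate_random()` — equiprobable placement without replacement.
* `generate_rich_club()` — one solid vertical band half the grid wide,
  wrapped toroidally in both directions: a single landmass maximizing
  like-near-like contact. Deterministic. Its interpretation variables at
  16 × 16 are $z_1 = 0.4375$, $z_3 = 0$, $y_2 = 0.03125$.
* `generate_scale_free()` — a hierarchy of compact islands with "far more
  small things than large ones": by default three 16-unit (4 × 4), five
  8-unit (4 × 2), and ten 4-unit (4 × 1) islands. Islands are placed
  largest-first at seeded random anchors (a shuffled scan over all
  anchors), each keeping a one-B-cell moat whenever any anchor admits one
  and relaxing to plain non-overlap otherwise; the generator retries the
  whole packing (default 25 restarts) and keeps the attempt with the most
  nearest-neighbor-connected A-components. Tall-narrow shapes were chosen
  over wide-flat ones because flat top/bottom island borders are exactly
  the A-B-A window geometry and would inflate $z_3$ beyond the island
  character the generator is meant to emulate.

A full-moat packing of all 18 default islands at 50% density on a 16 × 16
torus is infeasible (a column-budget argument over stacked height-4 bands
shows the 18 required gaps exceed the 16 available columns), so a few
contacts are unavoidable; the restart search typically leaves 10–14
separate components.

```{r patterns}
interpretation_variables(grid_fractions(generate_rich_club(16, 16)))
interpretation_variables(grid_fractions(generate_scale_free(seed = 1)))
```

These generators emulate the *statistical character* of manually designed
archetypes — a wrapped band versus an island hierarchy — not any
particular bitmap. What passing tests show is therefore that the method's
qualitative orderings (a massed pattern has higher $z_1$ and lower $y_2$
than an island pattern; minimized high-$h$ ensembles depart from the
closed form while $h = 1$ ensembles do not) are reproducible from the
generators' conditions; they do not certify agreement with any specific
hand-drawn grid.

## Numerical choices

* $\mathrm{Lf}(0) = 0$ by the limit convention; fractions below
  $10^{-300}$ are treated as exact zeros. Counted grids produce exact
  zeros routinely (a homogeneous grid has thirteen of them).
* The analytic solution's validity interval is open and guarded at
  $10^{-6}$ from each root.
* Swap ties ($\Delta\bar F = 0$) are rejected; descent is strict.
* Next-nearest "pairs" are counted as the $2N$ window instances ($N$
  same-row, $N$ two-rows-down). On grids with only 4 rows the two vertical
  partners of a site coincide; window counting keeps the $2N$ census and
  the $\sum_i\beta_i w_i = 1$ identity exact even there, whereas
  deduplicated pair counting would not. `nnn_sites(unique = TRUE)` is
  available when the deduplicated site set is wanted.
* Counting requires at least 4 rows and 3 columns so all window sites are
  distinct; smaller grids are rejected.
* Minimum seeds: every stochastic entry point (`generate_random`,
  `generate_scale_free`, `minimize_free_energy`, `perturb`, `sweep_h`,
  and the CLI) takes and records a seed; fixed seeds make runs
  bit-reproducible.

## Problem sizes used by the test suite

The suite verifies counting against a brute-force per-site classifier on
10,000 random grids up to 6 × 6 (exact integer equality), minimizes
ensembles of twenty 16 × 16 grids to convergence at $h = 1.65$ and
$h = 1.0$ for the departure-from-analytic property, and sweeps
$h = 0.8 \dots 1.8$ in steps of 0.1 with ten 16 × 16 trials per value.
These sizes match the 256-unit grids the method targets; the counting
identities are size-independent, so nothing about them is specific to
small grids.

## Limitations

* Only the horizontal-window triplet scheme is implemented; a scheme that
  also counted vertically oriented triplets would need a different census.
* Greedy strict-descent swapping stalls in local minima; there is no
  annealing or uphill acceptance, and no topography-aware proposal
  mechanism. Converged states at high $h$ are characteristic of the
  dynamics as much as of the free-energy surface — which is precisely the
  regime the departure-from-analytic property documents.
* No closed form exists when both $\varepsilon_0 \neq 0$ and
  $\varepsilon_1 \neq 0$; the package offers minimization, not a solver,
  in that regime.
* Boundary conditions are toroidal only, and rows must come in even
  counts.
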