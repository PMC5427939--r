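---
title: "Robust constraint-based analysis of metabolic networks with rampflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust constraint-based analysis of metabolic networks with rampflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampflux)
```

## The model

Flux balance analysis (FBA) treats a cell's metabolism as a linear system at
steady state: with stoichiometric matrix $S$ (metabolites by reactions),
flux vector $v$ and bounds $L \le v \le U$, it solves

$$\max \{ v_{\mathrm{Growth}} : S v = 0,\; L \le v \le U \}.$$

Both premises — exact steady state and deterministic coefficients — are
idealizations.  The biomass (growth) reaction in particular carries
empirically inferred, non-integer coefficients that vary across the cells of
a culture.  `rampflux` implements the robust counterpart (RAMP) in which
each steady-state equality becomes a chance constraint.  Writing the rate of
change of metabolite $i$ over a culture as approximately normal with mean
$\mu_i$ and standard deviation $\sigma_i$, the requirement
$P(-M_i \le \mathrm{d}[x_i]/\mathrm{d}t \le M_i) \ge 1 - 2\varepsilon$
becomes, given $q$ discrete scenarios $\hat S_i$ (rows $S_{ik}$) with
probabilities $p_i$:

$$\mu_i = p_i^T \hat S_i v, \qquad
  \sigma_i = \lVert R_i v\rVert / \delta_{1-\varepsilon}, \qquad
  R_i = \delta_{1-\varepsilon}\, \sqrt{P_i}\,(I - e\,p_i^T)\,\hat S_i,$$

and the robust constraint is the pair of second-order-cone inequalities

$$\lVert R_i v\rVert - M_i \;\le\; p_i^T \hat S_i v \;\le\; M_i - \lVert R_i v\rVert .$$

Equivalently, $v$ must satisfy $S_i v \le M_i$ for *every* row in the
uncertainty set $\{p_i^T\hat S_i + u^T R_i : \lVert u\rVert \le 1\}$.  The
bound $M_i$ is the permitted deviation from steady state, $\delta_{1-\varepsilon}$
the standard-normal percentile enforcing the probabilistic guarantee
(default 3).

Two properties shape the implementation and the tests:

* **FBA as a limit.** As the scenario spread and the $M_i$ vanish, the robust
  feasible set collapses onto $Sv = 0$ and the robust optimum converges to
  the FBA optimum.  The suite verifies this on seeded fixtures by scaling
  the proportional spread through six orders of magnitude.
* **Neither relaxation nor restriction.** The worked two-flux example
  (`toy_example()`) exhibits a point on the FBA line that the robust region
  rejects, and off-steady-state points that it accepts.

## Scenario models

All builders put uncertainty in the growth (biomass) column only, mirroring
the standard computational practice for this method; the low-level matrix operations
(`mean_row()`, `deviation_matrix()`) accept arbitrary scenario rows.

* `build_model1()` — *digit-level (default)*: each nonzero growth
  coefficient is perturbed in its first unspecified decimal digit, by
  $\pm\eta\cdot 10^{-d}$ for $\eta = 0, 1, 2$, where $d$ is one more than
  the number of printed decimals (`infer_digit_step()`).  Probabilities are
  the reference constants $(0.0351, 0.2389, 0.4520, 0.2389, 0.0351)$, which
  sum to exactly 1.  These are *not* the literal standard-normal band masses
  for cut points $\pm 1/2, \pm 3/2$ (those would be 0.0668 / 0.2417 /
  0.3829); we keep the reference constants because they reproduce the
  reference scenario tables exactly, and expose
  `recompute_probabilities = TRUE` for the literal bands.  $\delta = 3$.
* `build_model2(rho)` — digit-level steps scaled by an integer
  $\rho \in 1..9$; beyond 9 a coefficient could change sign, so larger
  values are rejected.
* `build_model3(sigma)` — *proportional*: scenarios
  $(1 + \eta\sigma)\,c$ for $\eta = -1, -\tfrac12, 0, \tfrac12, 1$.  The
  perturbation is the *factor* $(1 \pm \sigma)$ on the coefficient, not an
  additive $\pm\sigma$: only the factor reading makes $\sigma \to 0$
  collapse the model onto FBA, which the theory requires.
* `build_model4(epsilon2)` — digit-level scenarios with
  $\delta = \Phi^{-1}(1 - \varepsilon)$ for total tail mass
  $2\varepsilon \in (0, 1)$.
* `build_single_coefficient(target, sigma)` — the proportional family
  applied to one metabolite's growth coefficient only; the probe used by
  the maximal-uncertainty search.

Every family is symmetric, so the scenario mean reproduces the stated
coefficient exactly — the FBA matrix is recovered as the expectation.
Zero coefficients receive no scenarios (no "first unspecified digit"
exists).  Digit inference uses the printed decimal text where supplied and
otherwise the shortest round-tripping decimal of the stored double.

## Computational paths

**Linearized LP (default).**  When only the growth column is uncertain,
$\lVert R_i v\rVert = r_i\, v_{\mathrm{Growth}}$ with the scalar
$r_i = \lVert \delta \sqrt{P_i}(I - e p_i^T)\, s_i \rVert$
(`growth_norm_coefficient()`), and each cone constraint is exactly the
linear pair
$p_i^T \hat S_i v \mp r_i v_{\mathrm{Growth}} \gtrless \mp M_i$.
This requires $v_{\mathrm{Growth}} \ge 0$, which `assemble_linear_ramp()`
enforces via the lower bound; growth is nonnegative in all experiments here.
The linear path is the one that scales and is numerically stable.

**Cone path.**  `assemble_socp_ramp()` keeps the full $R_i$ matrices and
`solve_ramp()` then runs an outer-approximation loop: solve the current LP
relaxation, and for every violated cone constraint add the most violated
member of its uncertainty set (the cut $u = R_i v / \lVert R_i v\rVert$,
which is precisely `sample_uncertainty_constraint()` at the aligned
direction).  This is exact on convergence and is used for the worked
example, for general scenario rows, and as a cross-check of the linear
path (they agree to $10^{-6}$ on the fixtures).  It is intended for small
instances.

**LP engine.**  No linear-programming package is available in the
deployment environment, so the package carries a dense two-phase simplex
with Dantzig pricing, a Bland's-rule fallback after 500 iterations
(anti-cycling), pivot tolerance $10^{-9}$, and periodic refactorization of
the tableau from the original columns.  Refactorization matters: the robust
systems are heavily degenerate (paired rows that differ only in a tiny
$r_i$ term), and error accumulated across rank-one updates otherwise
corrupts the pricing step.  The test suite cross-checks the engine against
brute-force vertex enumeration on random instances.  Quadratic objectives
go through `quadprog`.

**Calibrating $M$.**  `fit_M()` solves
$\min \lVert M\rVert_1$ subject to the robust constraints,
$v_{\mathrm{Growth}} \ge \gamma^*$ (the FBA optimum), bounds and $M \ge 0$,
jointly in $(v, M)$ — the smallest total departure from steady state that
preserves the FBA growth rate.  Two numerical choices:

* The returned $M$ is recomputed analytically from the certifying flux
  vector as $M_i = \lvert p_i^T\hat S_i v\rvert + r_i v_{\mathrm{Growth}}$.
  The binding rows have dual prices on the order of $1/r_i$, so LP-level
  rounding in $M$ (harmless in itself) would otherwise be amplified into
  the recovered growth rate; the analytic recomputation is exact to machine
  precision and keeps the calibration identity
  $\text{robust growth} = \gamma^*$ within $10^{-6}$ relative even when the
  scenario spread is $10^{-7}$ of the coefficient.
* A target $\gamma^*$ above the FBA optimum is rejected as infeasible:
  larger growth could formally be bought with extra steady-state slack, but
  that would defeat the calibration's purpose (matching, not exceeding, the
  deterministic optimum).

Ties among alternative optimal $M$ are broken by the solver; uniqueness is
not guaranteed and not needed by any downstream step.

## Gene essentiality

`screen_knockouts()` removes, per gene, every reaction whose
gene-protein-reaction rule evaluates false (bounds set to zero; columns are
kept so indexing is stable), re-solves, and calls a gene essential when
knockout growth falls strictly below 50% of wild type (configurable).
Infeasible or failed knockout solves count as zero growth.  For the robust
screen, $M$ is fitted once on the wild type and held fixed across
knockouts: re-fitting per knockout would re-anchor the robust model to each
mutant's own FBA optimum and erase the comparison (a `refit_m` switch
exposes the alternative).

`max_sigma_search()` asks how much uncertainty a single biomass coefficient
tolerates before the robust essential-gene set departs from the FBA set:
starting at $\sigma = 10^{-4}$, double until the sets first disagree, then
binary-search the transition to within $10^{-4}$.  Set comparison is exact
equality.  If doubling passes $10^{26}$ without a mismatch only a lower
bound is known (`bounded = FALSE`) — the behaviour of biomass components
that are freely available in the environment and imported at no metabolic
burden, reproduced by the `free_uptake_network()` fixture.

## Flux fitting

`fit_fluxes_ramp()` / `fit_fluxes_fba()` minimize
$\lVert v - v_{\mathrm{EXP}}\rVert^2$ over the measured coordinates only,
subject to the robust (respectively strict steady-state) constraints and a
growth floor $v_{\mathrm{Growth}} \ge \theta\gamma^*$ with $\theta = 0.9$
by default — measured cultures need not be fully optimized.  Only measured
coordinates are penalized (fitting a handful of central-carbon fluxes must
not drag thousands of unmeasured fluxes toward zero).  Because `quadprog`
requires a positive-definite quadratic form, unmeasured coordinates carry a
$10^{-10}$ ridge; among degenerate optima this acts as a minimal-norm
tie-break and perturbs the objective by under $10^{-7}$ at the bound
magnitudes used here.  Measurement standard deviations are accepted but
unused by the default unweighted objective.  `mse()` reports
$\lVert v_{\mathrm{fit}} - v_{\mathrm{EXP}}\rVert^2 / N$; `compare_flux_fits()`
also reports the robust/FBA MSE ratio.

## Scenario-possibility test

For an optimal flux vector $\hat v$, a scenario family is *biologically
possible* exactly when each row's scenario values
$S_{ik}\hat v$ (over the nonzero fluxes) coincide — i.e.
$\hat S_i' \hat v' = \alpha_i e$.  `biologically_possible()` implements the
identical-components test and reports $\alpha_i$.  The theory's side
condition $\alpha_i \ne 0$ sits uneasily with mean-system feasibility
(which forces $p_i^T(\alpha_i e) = \alpha_i = 0$), so rows with
$\alpha_i \approx 0$ are flagged rather than rejected.

## Synthetic fixtures

`random_network()` generates the study conditions for all property tests:
a backbone chain routes a capacity-10 mmol/gDW/h uptake (the standard
glucose-limited minimal-medium setting) through intermediates into a
biomass reaction with 1–6-decimal coefficients, guaranteeing a positive FBA
optimum by construction; around it, integer-stoichiometry side reactions
(never mass-creating; only balanced ones reversible), a fixed-flux
two-cycle standing in for the ATP-maintenance implied equality, and random
boolean gene rules over a six-gene pool.  Default sizes are 8 metabolites by
14 reactions — large enough to exercise reversibility, implied equalities
and gene redundancy, small enough that the full acceptance sweep (20
networks, seven spread levels each) runs in seconds.  What these fixtures do
*not* emulate: genome-scale degeneracy structure, compartments, or realistic
pathway topology; passing tests certify the algebra and the algorithms, not
biological predictions on real reconstructions.  `parallel_path_network()`
places a knockout of intermediate severity (a branch at 45% of uptake
capacity) so the essentiality call flips at a closed-form uncertainty level
— the transition the sigma search must locate.

`random_essentiality_labels()` flips FBA-screen truth at a known rate so
confusion matrices have known expected cells.

## Numerical choices and limitations

* Feasibility audits use $10^{-9}$ absolute slack tolerance; growth-rate
  equality claims use $10^{-6}$ relative.  Fixture sweeps show the
  calibration gap is solver noise below $10^{-6}$, so monotonicity of the
  FBA-limit gap is asserted at that resolution.
* Infinite bounds map to $\pm 1000$ (COBRA convention), configurable.
* Reversibility needs no special handling: a reaction is reversible iff
  $L_j < 0 < U_j$.
* The general multi-column cone problem at genome scale is out of scope
  (the linearized path is the production path); the cone path is a
  small-instance tool.
* Genome-scale reproductions (iJO1366 / iAF1260 essentiality tables,
  per-coefficient maximal multipliers, experimental-flux MSEs) require
  external model and measurement downloads and are not part of the test
  suite; the screens, searches and fits those studies use are exactly the
  functions exercised here on fixtures.
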