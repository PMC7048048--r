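---
title: "Methods: thermodynamic constraint analysis and kinetic ensembles in thermokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic constraint analysis and kinetic ensembles in thermokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

# Scope

`thermokin` implements a complete modeling stack for thermodynamically
curated constraint-based models of compartmentalized bacterial metabolism:

1. flux balance analysis (FBA) and thermodynamics-based flux analysis (TFA)
   as mixed-integer linear programs;
2. a compartment-resolved scheme for integrating whole-cell metabolite
   concentration measurements;
3. thermodynamic variability analysis (TVA) and directionality fixing;
4. metabolic-task-driven MILP gap-filling;
5. Monte-Carlo ensembles of log-linear kinetic models with metabolic
   control analysis (MCA);
6. decision-tree refinement of kinetic parameter ranges;
7. study drivers: knockout-response analysis, an increased-ATP-demand
   sweep with a cap-sensitivity grid, and reduced-vs-reference consistency
   checks.

Everything can be exercised end to end on a synthetic two-compartment
network with a known nonlinear kinetic ground truth, so every nontrivial
computation in the package has an independent oracle.

# The TFA model

For each reaction $j$ the net flux is split as $v_j = F_j - R_j$ with
$F_j, R_j \ge 0$ and direction binaries $z_j^+, z_j^- \in \{0,1\}$,
$z_j^+ + z_j^- \le 1$, $F_j \le M z_j^+$, $R_j \le M z_j^-$. Each species
$i$ carries a log-concentration variable $u_i = \ln C_i$ (mol/L), bounded
by physiological limits $C \in [1\,\mu M,\ 50\,mM]$ by default. For every
reaction with a transformed standard Gibbs energy annotation,

$$\Delta_r G'_j = \Delta_r G'^\circ_j + RT \sum_i s_{ij} u_i,$$

and flux in a direction is admitted only when $\Delta_r G'$ is strictly
negative in that direction, via big-M coupling with a strictness margin
$\varepsilon_G = 10^{-6}$ kJ/mol. Reactions without an annotation get
flux-only treatment.

Numerical choices (the annotations are silent on all of them): the flux
big-M is 100 mmol/gDCW/h above the largest finite bound; the Gibbs big-M is
per reaction, $|\Delta_r G'^\circ| + \text{err} + RT(\ln UB - \ln LB)
\sum_i |s_{ij}| + 1$, which keeps the LP relaxation tight; water and
protons are excluded from the $RT\sum s u$ term (their activity is taken as
folded into the transformed energies); annotation uncertainties widen the
$\Delta_r G'^\circ$ by $\pm$ one reported error by default
(`use_drg_err = FALSE` ignores them). The temperature default is 298.15 K
and enters only through $RT$.

The LP/MILP layer is a thin pluggable interface; the shipped backend
serializes batches of problems to JSON and solves them with HiGHS through
scipy (`inst/python/milp_solve.py`). Batching matters because variability
analysis and the study sweeps solve hundreds of small related programs;
one backend invocation solves them all. HiGHS is deterministic, which the
test suite asserts (identical objectives to $10^{-9}$ on repeated solves).

# Compartment-resolved measurement integration

Metabolomics protocols measure whole-cell concentrations, while the model
distinguishes the same metabolite in cytosol and periplasm. With
compartment volume fractions $\alpha_i$ (defaults 0.88 cytosol, 0.12
periplasm; renormalized over the compartments where the metabolite
occurs), the whole-cell concentration is the volume-weighted mean
$C_M = \sum_i \alpha_i C_{Mi} / \sum_i \alpha_i$. Forcing the measured
interval on every compartment separately is too strict; `thermokin`
instead emits, per measured metabolite present in $i$ compartments,
exactly $i + 2$ constraints:

* widened per-compartment bounds
  $\overline{C_{Mi}} = \min\!\big(\tfrac{\overline{C_M} - (1-\alpha_i)LB}
  {\alpha_i},\, UB\big)$ and
  $\underline{C_{Mi}} = \max\!\big(\tfrac{\underline{C_M} -
  (1-\alpha_i)UB}{\alpha_i},\, LB\big)$ — the most extreme value one
  compartment can take while the rest of the cell sits at the opposite
  physiological limit;
* the Jensen inequality for the concave logarithm,
  $u_M \ge \sum_i \alpha_i u_i$, linking an auxiliary whole-cell variable
  $u_M = \ln C_M$ to the compartment variables; and
* the measured bounds on $u_M$ itself.

The relaxation is exact in one direction: any true compartment assignment
whose volume-weighted mean lies in the measured window satisfies all
emitted constraints (a property test samples 10,000 such assignments). It
is deliberately one-sided: the concave $\log$ admits a linear *lower*
bound on $u_M$ but no linear *upper* bound in terms of the $u_i$, so the
measured lower bound reaches the compartment variables only through the
widened per-compartment bounds. A single-compartment metabolite
degenerates to the plain measured bound. For comparison,
`integrate_measurements(..., compartmentalized = FALSE)` applies the
classic shared-concentration scheme.

Measured extremes outside the physiological window are clipped with a
warning.

# Gap-filling

A metabolic task (growth floor, uptake window, optionally a concentration
window — the latter requires TFA, since it speaks about $u$ variables) that
is infeasible on a host model is repaired from a donor model's reactions.
Candidates are gated by binaries ($-M y_k \le v_k \le M y_k$) and
$\sum_k y_k$ is minimized; alternate minima are enumerated with integer
cuts (default cap 10). Donor reactions identical to a host reaction up to
positive scaling are dropped beforehand; a reversed copy of an
irreversible reaction is kept, because it adds a capability the host lacks.
`gapfill_bruteforce()` re-verifies minimality by exhaustive subset
enumeration, batched into a single solver call; the planted synthetic
instance is solved both ways in the tests.

# Kinetic ensembles and control analysis

A TFA solution supplies the reference state: fluxes $v^*$, concentrations
$C^*$ and Gibbs energies, hence per-reaction displacements
$\Gamma_j = \exp(\Delta_r G'_j / RT) \in (0,1)$ after orienting each
reaction along its flux. Extracellular metabolites are demoted to
parameters (their balances are dropped), water balances are removed, and
reactions with $|v^*| < 10^{-6}$ are frozen out of the kinetic network.
The retained fluxes are repaired to satisfy the retained mass balances to
machine precision by a minimal-norm correction.

Mechanisms: transport and diffusion steps are mass action; enzyme-catalysed
reactions get generalized reversible kinetics with independent binding
sites, the reversible uni-uni Michaelis–Menten mechanism being the
one-substrate/one-product special case. Irreversible steps (no
thermodynamic annotation) carry sites for substrates only. With site
saturations $\sigma \in (0,1)$ and multiplicities $m = |s_{jk}|$, the
scaled elasticities are

$$\varepsilon_{jk} = \max(-s_{jk}, 0) \;-\;
  s_{jk}\frac{\Gamma_j}{1-\Gamma_j} \;-\; m\,\sigma_{jk},$$

the saturation term applying to saturable sites only. Saturations are
sampled uniformly on $(0,1)$ per unknown site; slots with an experimentally
known Michaelis constant are pinned at $\sigma = C^*/(C^* + K_m)$, and
unknown $K_m$ values are back-calculated as $K_m = C^*(1-\sigma)/\sigma$.
References with $\Gamma > 0.999$ in any sampled reaction are rejected — the
$1/(1-\Gamma)$ terms blow up at equilibrium — with the margin
$\delta = 10^{-3}$ chosen to keep elasticities below $\sim 10^3$.

Conservation relations (e.g. adenylate and pyridine-nucleotide totals) are
handled by the link decomposition $N = L N_R$; because elasticities are
logarithmic derivatives, the link matrix is weighted into log space,
$\tilde L = \mathrm{diag}(1/x^*_{\text{full}})\, L\,
\mathrm{diag}(x^*_{\text{ind}})$. Stability of a member is judged by the
eigenvalues of $J = \mathrm{diag}(1/x^*)\, N_R\, \mathrm{diag}(v^*)\, E\,
\tilde L$; unstable members are discarded and resampled (the acceptance
rate is reported; it is ~95% on the synthetic network). Control
coefficients use enzyme activities as the perturbation basis:

$$C^X = -\tilde L\, (N_R\, \mathrm{diag}(v^*)\, E\, \tilde L)^{-1}
  N_R\, \mathrm{diag}(v^*), \qquad C^J = I + E\, C^X,$$

whose rows satisfy the summation theorems (flux rows sum to 1,
concentration rows to 0) identically — the suite checks every member to
$10^{-8}$. On the two-step pathway with $\varepsilon = (-1, 0.5)$ this
reduces to the textbook closed form $C^J = (1/3, 2/3)$.

## The ground-truth oracle

`generate_ground_truth_kinetics()` builds a full nonlinear ODE model whose
fixed point is exactly a chosen TFA steady state: the minimal-total-flux
solution at 99% of maximal growth supplies $v^*$; a second solve pushes
every active $\Delta_r G'$ as far from zero as possible (maximizing the
smallest margin, capped at 10 kJ/mol) so no reaction sits near
equilibrium, and then — retaining 90% of that margin — pulls every
log-concentration towards the centre of the physiological window (an L1
objective). The centring matters for the oracle role: concentration
profiles parked at the window extremes give metabolite pools turnover
times up to ten orders of magnitude apart, leaving the fixed point too
ill-conditioned for finite-difference validation in double precision;
centred profiles keep the relaxation spectrum within a workable range.
True saturations are drawn on $(0.25, 0.75)$, and the rate
constants are solved so each rate law equals $v^*_j$ at $C^*$. Perturbed
steady states are found by stiff integration (`deSolve`) into the
attraction basin followed by Newton polishing on the reduced balance
equations, with the Newton Jacobian obtained by complex-step
differentiation of the rate-law code — numerically exact and sharing no
code with the analytic elasticity formulas. Enzyme activities are
perturbed by $\pm 0.1\%$ (central differences with one Richardson
extrapolation step, needed because some concentration-control
coefficients on the synthetic network exceed 200 in magnitude and a
one-sided step leaves the linear regime), and the finite-difference
control coefficients agree with the analytic ones to better than 1%.

# Refinement of parameter ranges

Members of an ensemble are labeled consistent or inconsistent against a
response-sign specification (a data frame of target/enzyme/sign triples
checked against the stored control coefficients, or an arbitrary labeling
function for planted-rule studies). A single `rpart` decision tree (depth
$\le 6$, leaf size $\ge 50$) is trained on the $\log_{10} K_m$ features;
the highest-support leaf of the consistent class with purity $\ge 0.95$
supplies axis-aligned ranges, intersected with the originally sampled
ranges and ranked by variable importance (at most 7 returned by default,
matching the scale of parameter sets such analyses typically surface). A
fresh ensemble is then sampled with saturations restricted to
$\sigma \in [C^*/(C^*+K_m^{hi}),\ C^*/(C^*+K_m^{lo})]$ per refined slot,
and the consistency fraction is recomputed. On a planted single-threshold
rule at $n = 5000$ the threshold is recovered to well within 10% and the
consistency fraction rises from a few percent to ~1.

# The synthetic study system

`generate_network(synthetic_spec())` builds `d2_mini`, a 31-reaction,
two-compartment (cytosol 0.88 / periplasm 0.12) caricature of central
carbon metabolism in a glucose-grown pseudomonad: periplasmic glucose
oxidation to (keto)gluconate feeding gluconate/ketogluconate kinases, a
direct import/hexokinase route, an Entner–Doudoroff-like branch, a pentose
phosphate-like branch whose transketolase analog (TKT2) gates triose
phosphate replenishment, a lumped lower glycolysis, a TCA-like cycle, an
electron transport chain with an ATP synthase analog (cap 70 mmol/gDCW/h),
an ATP maintenance drain, oxygen uptake (cap 40) and by-product secretion.
Standard-energy annotations come from a three-level palette
($-1$, $-10$, $-30$ kJ/mol, seeded jitter $\pm 0.5$), placing the
transketolase and transhydrogenase analogs near equilibrium and the
committed steps far from it. The biomass reaction consumes triose
phosphate, pyruvate, acetyl-CoA, pentose phosphate, 60 ATP and 15 NADPH
per unit growth, scaled so that wild-type growth is ~0.75 1/h at a glucose
uptake of 10 mmol/gDCW/h — the flux scale of the organism the network
emulates.

The network reproduces the qualitative phenomena the studies need, with
exhaustive oracles still tractable: the transketolase directionality gates
ED-branch essentiality (blocked towards triose production, the ED
knockouts become lethal; free, they are bypassed); the ATP-demand sweep
shows a monotone rise of the minimal glucose uptake to a cap-bound peak
followed by decline of both uptake and growth; on the cap-sensitivity grid
the peak magnitude is set by whichever cap binds first (in this network
the ATP synthase flux is twice the oxygen flux through the
ETC stoichiometry, so an O2 cap of 30 binds before ATPS caps of 70–80),
while raising the ATP synthase cap moves the peak to higher ATP demand.

Measurements are generated from the ground truth by volume-weighted
mixing, log-normal noise ($\sigma_{\log_{10}} = 0.1$) on the midpoint and
a $\times 1.5$ interval half-width; the interval always contains the true
whole-cell value, so the ground-truth state remains feasible for any
problem built on generated measurements — the invariant the end-to-end
tests rely on. What the generator does *not* emulate: measurement bias,
correlated errors across metabolites, missing values, thermodynamic
annotation errors beyond the stated $\pm$err, or enzyme regulation beyond
mechanism stoichiometry. A passing suite therefore validates the
machinery, not the biology of any particular organism.

One property of `d2_mini` is worth flagging because it differs from
genome-scale behavior: the correlation between growth-control and
cytosolic-ATP-concentration-control coefficients across enzymes is
strongly *negative* here. Growth in the toy is ATP-limited (the biomass
reaction consumes 60 ATP), so enzymes that raise growth draw the ATP pool
down. At genome scale, where ATP production rather than consumption is
limiting, the same two vectors correlate positively. The
`stress_control_study()` machinery computes the correlation either way;
its sign is a property of the network, not of the method.

# Problem sizes and determinism

The shipped analyses run at deliberately desk-scale sizes: ensembles of
1000–5000 members on the 31-reaction network, sweeps over ~20 ATP-demand
grid points, sensitivity grids of a few cells, exhaustive gap-fill
verification over subsets of ≤ 11 candidates. All randomness flows from a
single integer seed (network jitter, measurement noise, true saturations,
ensemble sampling), and every study is a pure function of (model, config,
seed); rerunning bit-reproduces all outputs.

# Known limitations

* Membrane potential is not modeled; transport reactions carry only their
  annotated (or absent) standard energies.
* The MILP backend requires a `python` interpreter with scipy on the PATH;
  there is no in-process fallback.
* Loopless-FBA is not provided separately: thermodynamic coupling already
  excludes infeasible cycles among annotated reactions, but cycles of
  unannotated reactions are only suppressed by total-flux minimization.
* The refinement step extracts ranges from a single high-purity leaf;
  disjunctive consistent regions (two separate boxes) are truncated to the
  better-supported one.
* Gene rules are optional; when absent, gene knockouts degenerate to
  reaction knockouts.
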