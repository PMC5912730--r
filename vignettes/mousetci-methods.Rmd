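---
title: "Methods: pharmacokinetic modelling and brain TCI of propofol in mice"
author: "mousetci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacokinetic modelling and brain TCI of propofol in mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousetci)
```

## The model

`mousetci` treats propofol disposition in the mouse as a three-compartment
mammillary system: compartment 1 is blood (concentration $x_1$, µg·mL⁻¹),
compartment 2 is brain ($x_2$, µg·g⁻¹), compartment 3 lumps all other
tissue ($x_3$). Drug enters and leaves only through blood:

$$
\begin{aligned}
\dot x_1 &= -(k_{12}+k_{13}+k_{10})\,x_1 + k_{21} x_2 + k_{31} x_3
            + I(t)/s_{\mathrm{inf}} \\
\dot x_2 &= k_{12} x_1 - k_{21} x_2 \\
\dot x_3 &= k_{13} x_1 - k_{31} x_3
\end{aligned}
$$

with first-order rate constants $k_{ij}$ (min⁻¹), elimination $k_{10}$ from
blood only, and a weight-normalized infusion $I(t)$ in mg·kg⁻¹·min⁻¹.
$s_{\mathrm{inf}}$ (L·kg⁻¹) is the apparent central volume per kg body
weight: it converts the infusion rate into a concentration rate in blood,
and is the only place body size enters — the model is otherwise fully
weight-normalized. Brain µg·g⁻¹ and blood µg·mL⁻¹ are treated as
numerically commensurate (unit tissue density).

The packaged reference constants (`mouse_pk_params()`) are
$k_{12}=1.55$, $k_{21}=2.71$, $k_{13}=0.22$, $k_{31}=0.04$,
$k_{10}=0.07$ min⁻¹ and $s_{\mathrm{inf}}=0.35$ L·kg⁻¹. Their eigenvalues
split into a fast blood–brain equilibration mode (≈4.4 min⁻¹, seconds), an
intermediate mode (≈0.21 min⁻¹, minutes) and a slow peripheral mode
(≈0.008 min⁻¹, a ~2 h time constant): transient behaviour is over in
minutes, full steady state takes hours.

## Simulation: two routes, one of them exact

Schedules are piecewise-constant rate vectors on a uniform grid
(`infusion_schedule`; 10 s is the TCI time unit, a bolus uses a 6-s grid so
its 15 mg·kg⁻¹ dose is represented exactly). Because the system is linear
and time-invariant, its solution over one constant-rate interval is given
exactly by the matrix exponential of a 4×4 augmented system matrix;
`simulate_lti` propagates that closed form interval by interval (compiled
code, exact to floating precision, no matrix inverse, so $k_{10}=0$ and
other singular configurations are handled). `simulate_pk` integrates the
same equations with an adaptive solver (deSolve, `rtol` 1e-8 / `atol`
1e-10), restarted at every rate changepoint so the discontinuous forcing
never crosses an integration step. The exact propagator is the reference:
the test suite requires the two routes to agree to 1e-6 relative and uses
`simulate_lti` everywhere a prediction feeds an objective, keeping the
fitting surface smooth. The initial state is zero (drug-naive animal at
infusion start).

Degenerate constants: with $k_{21}=0$ or $k_{31}=0$ the system still
integrates, but no finite steady state exists and `steady_state()` refuses
rather than returning an infinity. Under a constant rate $I$ with all
return paths open the closed forms are
$x_1 = I/(s_{\mathrm{inf}} k_{10})$, $x_2/x_1 = k_{12}/k_{21}$,
$x_3/x_1 = k_{13}/k_{31}$.

## Fitting

For animal $k$ with measurements $d_k$ at its sample times and model
predictions $p_k(\omega)$, the per-animal error is
$\varepsilon_k(\omega) = \lVert d_k - p_k \rVert_2^2 / n_k$ — blood and
brain residuals pooled with equal unit weight, normalized by the animal's
sample count so unevenly sampled animals contribute equally. The cohort
objective is the mean $G(\omega) = \tfrac1N \sum_k \varepsilon_k$. (The
unsquared reading — Euclidean distance over sample count — is available via
`squared = FALSE`; the squared norm is the default because it is the
quantity the normal-equations view minimizes and keeps the objective
smooth at zero residual.)

`fit_pk` minimizes $G$ subject to nonnegativity of all six constants:
L-BFGS-B on log-transformed parameters (box $[10^{-8}, 10^3]$ on the
natural scale), which enforces the constraint and conditions a search
across parameter decades. The multi-start design mirrors iterative
practice: 100 starting sets drawn log-uniformly (rate constants over
$[10^{-3}, 10]$ min⁻¹, $s_{\mathrm{inf}}$ over $[0.01, 5]$ L·kg⁻¹ —
spanning plausible PK magnitudes symmetrically in scale), a cheap first
pass over all starts, then the leading solutions polished at tight
tolerance (objective convergence factor `factr = 10`, i.e. ~1e-15
relative). Ties across starts break to the lowest objective, then earliest
start; the seed makes fits bit-reproducible. Up to the top 100 solutions
are retained so `refit_pk` can warm-start the next round after new
experiments arrive — a warm restart never returns a worse objective than
any reused start evaluated on the new cohort. A cohort with fewer samples
than parameters is flagged as under-determined (warning), since many
parameter sets then reach an equal objective.

## TCI planning

The planner exploits linearity the STANPUMP way: the brain response to any
schedule is the causal convolution of its rates with the brain impulse
response $h$ — the response to a unit-rate infusion over a single 10-s grid
step. A subtlety drives the design: $h$ peaks several steps *after* the
impulse, because drug must transit the blood before reaching the brain.
Solving each step only for its end-of-step concentration therefore
overshoots, and a pump cannot withdraw drug. `plan_tci` instead selects, at
every step, the largest rate (clipped to `[0, max_rate]`, default 150
mg·kg⁻¹·min⁻¹ — the loading-bolus rate, a physical pump bound rather than
an unbounded impulse) whose convolution-predicted brain concentration never
exceeds the target at any future grid point; a fixed-point polish re-checks
the peak after each closed-form solve (a no-op in exact arithmetic, a guard
against accumulated rounding). The plan therefore approaches the target
from below, reports `approach_end` — the first grid time from which every
prediction stays within the 5% maintenance tolerance — and fails loudly if
that exceeds the approach cap (default 5 min) under the rate ceiling. If a
disturbance ever places the prediction above target the rate floors at
zero and the excursion decays passively; such intervals are exempt from
the per-step tolerance but visible in `max_relative_deviation`.

For the reference constants and a 10 µg·g⁻¹ target the plan loads for ~20
s, completes its approach inside a minute, holds the prediction within 2%
of target, and its maintenance rate decays toward the analytic value
$s_{\mathrm{inf}} k_{10} (k_{21}/k_{12})\,\mathrm{target}$ (≈0.43
mg·kg⁻¹·min⁻¹ at 10 µg·g⁻¹) with the slow peripheral time constant.
`export_pump_schedule` converts mass rates to pump volumetric rates,
mL·h⁻¹ = rate × weight(kg) × 60 / drug concentration (default 10 mg·mL⁻¹).

## Validation statistics

* **Performance error**: $PE = (C_m - C_p)/C_p \times 100$ per sample;
  MDPE (median, bias) and MDAPE (median absolute, precision), with a
  seeded percentile bootstrap (10,000 resamples) for the MDPE 95% CI — the
  bootstrap method is a package choice; even-length medians average the
  central pair.
* **Drift slope**: ordinary least-squares slope of concentration on time.
  The default standard error is the literal field formula
  $\sqrt{S(c)/((n-2) S(t))}$ with $S(x)=\sum (x_i-\bar x)^2$ — note it
  uses the *total* sum of squares of the concentrations, not the residual
  sum, so it does not reduce to the textbook OLS slope SE except under a
  zero fitted slope; `se_method = "ols"` gives the textbook reading. The
  literal default is kept for fidelity to reported intervals; under a true
  zero slope the two coincide asymptotically, which is why the no-drift
  coverage simulation still attains nominal coverage.
* **Ljung–Box**: $Q = n(n+2)\sum_{j\le L} \hat\rho_j^2/(n-j)$ against
  $\chi^2_L$, implemented from the formula and validated against an
  independent reference implementation in the tests; default lag count
  $\min(10, n/5)$. Zero-variance residual series are rejected as
  degenerate.
* **Window comparison**: two-sided rank-sum test of the first versus last
  20 minutes of a one-hour infusion; exact permutation enumeration
  (midranks, ties handled) for combined $n \le 20$, normal approximation
  with tie correction otherwise.
* **Normalized moving statistics**: concentrations divided by target,
  sorted by time, summarized in sliding windows of 10 consecutive samples
  stepped by 1, reported at each window's median time.

## The synthetic-experiment generator

The generator exists so fitting, planning and validation are testable
without animals; it emulates the in-vivo designs, not the animals
themselves. Paradigms: a 15 mg·kg⁻¹ bolus (150 mg·kg⁻¹·min⁻¹ for 6 s), a
one-hour constant infusion at 2 mg·kg⁻¹·min⁻¹, and TCI sessions at 10 and
15 µg·g⁻¹. Sampling respects the in-vivo limits (≤8 brain biopsies, ≤3
blood draws per animal). Biopsy times are not published, so the defaults
are conventions: geometric spacing from 30 s after a bolus (early-dense,
where the fast kinetics live — with only late samples $k_{12}$ and
$k_{21}$ are identifiable only through their ratio) and even spacing
through constant/TCI infusions; blood draws are evenly spaced with a
terminal sample. Body weights come from a truncated-positive normal
(27.4 ± 1.5 g). Per-animal seeds derive deterministically from the master
seed; identical seeds give byte-identical cohorts.

Measurement noise is multiplicative mean-one lognormal with cv 12.5%,
motivated by the 10–15% spatial interquartile variability estimated for
serial brain biopsies. One calibration note: a lognormal with cv 0.125 has
an IQR/median of 16.8%, slightly above that band (the band's upper end
corresponds to cv ≈ 0.111); the cv default is kept and the calibration
test asserts the analytic lognormal value. What the generator does *not*
emulate: biopsy trauma, spatial concentration gradients, isoflurane
co-administration, hemodynamic change, assay drift — so passing tests
demonstrate correctness of the estimation and control machinery under the
stated statistical model, not robustness to those in-vivo effects.

For validation-style experiments `sim_experiment(..., plan_params = fit)`
lets the pump follow a *fitted* model while the simulated animal follows
the *true* kinetics — the exact situation a prospective validation cohort
probes.

## Problem sizes and numerical choices in the shipped checks

The test suite and the acceptance script use desk-scale designs chosen
once: the noise-free recovery cohort is one animal per paradigm (noise-free
replicates are identical, so more add no information) with the full 100
multi-starts; the noisy recovery study uses cv 12.5% with 20 animals and
25 starts; the Ljung–Box size simulation uses 2,000 replicates at
$n = 200$; the drift-coverage simulation 1,000 replicates; target-tracking
validation 5 animals per target. Relative tolerances: 1e-6 for
integrator-versus-oracle agreement, 2% for noise-free parameter recovery,
the planner's own 5% for maintenance accuracy.

## Known limitations

No population (mixed-effects) hierarchy — all animals share one
fixed-effect parameter set; no Bayesian uncertainty on the constants; no
effect-site link to neurophysiology (brain concentration is modeled
directly, which is the point of the approach); no closed-loop
measurement feedback; the pump interface stops at an exported rate table.
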