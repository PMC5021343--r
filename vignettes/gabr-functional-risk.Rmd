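---
title: "Quantifying functional risk of GABA-A receptor variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional risk of GABA-A receptor variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabrisk)
library(dplyr)
```

## The problem

Missense variants in GABA-A receptor subunit genes (*GABRs*) are common in
both epilepsy patients and the general population, and most of them have
never been characterized functionally. When a variant-bearing receptor is
expressed and probed with rapid GABA applications, its functional impact
shows up in a handful of quantitative readouts: the peak current density
(pA/pF), the activation onset and deactivation time constants of brief-pulse
currents, zinc sensitivity (a stoichiometry control), the GABA EC50, and —
at the structural level — how far a mutant model ensemble deviates from the
wild-type structure. `gabrisk` implements that entire analysis chain as
composable, tibble-first functions, together with a synthetic-data generator
so every stage can be exercised and validated without access to raw
recordings.

## The kinetic scheme behind the simulator

`simulate_current()` integrates a five-state Markov scheme

$$\mathrm{C} \underset{k_{off}}{\overset{2 k_{on} c}{\rightleftharpoons}}
  \mathrm{CA} \underset{2 k_{off}}{\overset{k_{on} c}{\rightleftharpoons}}
  \mathrm{CA_2} \underset{\alpha}{\overset{\beta}{\rightleftharpoons}} \mathrm{O},
  \qquad \mathrm{CA_2} \underset{r}{\overset{d}{\rightleftharpoons}} \mathrm{D}$$

with two sequential GABA binding steps, one open state and one desensitized
state. This is the smallest scheme that yields sigmoid concentration–response
curves, desensitization during long pulses, and independently tunable
activation (via $\beta$) and deactivation (via $k_{off}$ and $\beta/\alpha$).
Macroscopic current is $I(t) = N\,P_{open}(t)\,g\,(V_h - E_{rev})/1000$ pA.
The occupancy ODEs are integrated with a stiff-capable adaptive solver
(`deSolve::lsoda`, relative tolerance $10^{-8}$) because the rate constants
span several orders of magnitude; probability conservation is verified to
$10^{-8}$ in the tests. Solution exchange is modelled as an exponential
concentration relaxation with a 0.4 ms time constant, consistent with fast
perfusion systems whose tip exchange is a few hundred microseconds, and
traces are sampled at 10 kHz, the standard digitization rate. Recording noise
is additive i.i.d. Gaussian; no filtering is emulated, which is sufficient
for stress-testing the fitters but does not reproduce the correlated noise of
real rigs.

**The default rate constants are illustrative.** No kinetic parameters are
published for any specific receptor isoform, so the defaults were chosen once
to give wild-type-like macroscopic behaviour for a ternary
$\alpha\beta\gamma$ receptor: activation onset below 1 ms at 1 mM GABA, a
weighted deactivation time constant near 100 ms, peak density in the
700–900 pA/pF range for a 9 pF cell, and ~10% inhibition of the peak by
10 µM zinc (modelled as equilibrium open-channel block with a 90 µM apparent
IC50). They are a realistic test-bed, not parameter estimates.

A "variant" is a multiplicative perturbation of the wild-type rates:

```{r}
wt <- kinetic_scheme()
impaired <- make_variant_scheme(wt, c(beta_open = 0.3, koff = 3))
```

scales channel opening down threefold and agonist unbinding up threefold —
the combination that produces the gating-impaired phenotype of slowed
activation plus accelerated deactivation.

## Fitting macroscopic kinetics

`fit_exponentials()` fits $\sum_n a_n e^{-t/\tau_n} + C$ by
Levenberg–Marquardt least squares (`minpack.lm`), growing the model from one
to at most four components. An extra component is retained only when the
extra-sum-of-squares F test on the residuals is significant at `alpha_F`
(default 0.05 — the conventional reading of "significantly improved the
fit"). Three numerical choices matter:

* **Multi-start initialization.** Eight deterministic starts per component
  count, with log-spaced time-constant seeds sliding across
  $[\sim\!0.1\,\mathrm{ms}, T_{segment}]$ and amplitudes solved by linear
  least squares; when growing from $k$ to $k+1$ components the accepted
  $k$-component solution also seeds warm-start continuations. Ties are
  broken by lowest SSR, then fewest components (via the F test).
* **Sign-constrained amplitudes.** The fitted segments are monotone
  relaxations (rise to the peak, or decay from it), so all amplitudes in one
  fit are constrained to the sign of the dominant decay. Without this, tiny
  opposite-sign components chase individual noise excursions and the F test
  happily accepts them.
* **An identifiability guard.** A richer model is accepted only if its
  adjacent time constants differ by at least a factor of 2
  (`min_tau_ratio`). Exponential sums with closer time constants are
  numerically degenerate — the components trade amplitude almost freely — so
  such fits are treated as a re-parameterization of the simpler model, not
  as evidence for an extra component. The cost is reduced power to resolve
  genuinely close components, which we accept and document.

Segment rules (the windows are conventions, stated as such): the activation
window runs from the first crossing of 3× the baseline SD (with a
1%-of-peak floor so noiseless traces are handled) to the peak of the
5-point-median-smoothed trace; the deactivation window runs from the
post-removal peak to the end of the record. The activation onset $\tau$ is
reported as the weighted $\tau$ of the activation fit when it is
multi-component; a mono-exponential convention (`activation_tau = "mono"`)
is available since published "activation onset" columns do not state which
was used. The single-component model is always attempted even on short
activation windows (a 3 ms window at 10 kHz has only ~30 samples); the
10-points-per-parameter rule gates growth to richer models.

Derived statistics follow their defining arithmetic: the weighted time
constant $\sum a_n\tau_n / \sum a_n$, current density $|I_{peak}|/C_m$
(reported as a positive magnitude), zinc inhibition
$100(1 - I_{Zn}/I_{ctrl})$, and the gating impairment ratio
$(\tau^{act}_{var}/\tau^{act}_{wt}) / (\tau^{deact}_{var}/\tau^{deact}_{wt})$,
where values above 1 mean the variant slowed opening and hastened closing.

## Concentration–response analysis

`fit_hill()` fits the four-parameter logistic in log concentration by
deterministic multi-start Levenberg–Marquardt. Each curve is normalized to
its own saturating response. The loss/gain-of-function call uses the
LogEC50 change ratio $\log_{10} EC50_{var} / \log_{10} EC50_{wt}$ **with
EC50s in molar**: on that scale a 10-fold potency loss from 0.2 µM gives a
ratio of ≈0.85, matching the magnitude such ratios take in practice, whereas
µM units would not. Ratios below 1 are loss-of-function. The companion
`fold_change()` is the plain EC50 quotient, and the two agree in direction
for all sub-molar EC50s (a property test sweeps this). Per-cell ratio
averaging is supported by mapping `fit_hill()` over cells and averaging the
ratios, since the exact per-cell protocol behind published ratio SEMs is not
stated.

## Association statistics

`fisher_exact_2x2()` implements the two-tailed Fisher exact test by the
minimum-likelihood rule: all tables with the observed margins whose
hypergeometric probability does not exceed the observed table's (with a
$10^{-7}$ relative tolerance so floating-point noise cannot flip borderline
tables) contribute to p. Summation is in log space. An exhaustive test
compares it against direct factorial enumeration for every 2×2 table with
total at most 40.

`compare_to_wt()` provides the classical unpaired two-tailed Student t test
and one-way ANOVA followed by Dunnett's many-to-one comparisons. The Dunnett
adjusted p-value is $1 - P(\max_i |T_i| \le |t|)$ where the $T_i$ share the
wild-type mean and the pooled error. We evaluate that probability by
deterministic Gauss–Legendre quadrature of the classical double integral
over the control-mean and pooled-SD factors (96 nodes each), which handles
unbalanced group sizes exactly, is reproducible without a Monte-Carlo seed,
and agrees with the `multcomp`/`mvtnorm` reference implementation to better
than $10^{-3}$ in the tests. A 10,000-replicate null simulation confirms the
familywise flag rate sits at 5%.

`classify_variant()` turns the statistics into the two catalog flags:
`reduced_current` when the density comparison is significant with a negative
difference, and `gating_defect` when the impairment ratio reaches a
configurable threshold (default 1.2). Computing the ratios from the
published per-cell summary kinetics, the non-defective calls top out near
1.17 and the defective ones start near 1.24, so 1.2 separates them — with
one known discordant borderline case (α4 H372P, ratio ≈1.25 yet called
intact), which is why the threshold is a parameter and not a constant.
Whether published reduced-current calls used Dunnett-adjusted or per-test
significance is not stated; both routes are available via `test=` in
`compare_to_wt()`.

## Variant catalogs

Variants are identified by their (gene, protein substitution) key.
`unique_variants()` implements the mutually-exclusive case/control
definition, `filter_rare()` the strict <0.5% rarity cut, and
`summarize_occurrences()`/`domain_distribution()` the cohort summaries, with
percentages rounded half-up so 12.5% prints as 13%. Two packaged TSVs under
`extdata` carry the 32 functionally characterized variants (with PolyPhen-2
categories and scores, domains, interface sides and functional flags) and
the 24 unique case-cohort variants with occurrence counts; interface-side
annotations are a static per-variant table (principal/complementary/none),
as no structure computation is needed to reproduce them. Catalogs from the
three *GABR*s with uncertain brain expression (*GABRE*, *GABRP*, *GABRR2*)
are retained on ingestion and can be excluded by ordinary filtering. Note
one bookkeeping subtlety the package inherits from its sources: "33" counts
unique-variant *occurrences* across 24 distinct variants, and the summary
keeps that distinction explicit.

## Structure perturbation scoring

`ensemble_rms()` scores a mutant ensemble against the wild-type reference:
the ten lowest-energy members (the conventional choice even when up to
twenty are generated) are each superposed by a **single global Cα Kabsch
fit**, per-element RMS deviations are computed separately over side-chain
heavy atoms (everything but N, CA, C, O) and backbone heavy atoms, and the
per-member values are averaged. Elements with a mean RMS at or above 0.5 Å
are flagged; `classify_perturbation()` calls the pattern *local* when every
flagged element lies in the mutated subunit and *global* otherwise. The
global-superposition frame is deliberate: fitting each element locally would
hide propagated domain motions, which are exactly what distinguishes global
perturbations. Glycine-only elements report an absent (NA) side-chain RMS
rather than zero. Element definitions (loops A–G, β-strands, Cys-loop,
pre-M1, M1–M4, M2–M3 linker, ...) are an editable per-residue table
(`element_map_from_ranges()`), since different templates number residues
differently; the repack radius of the upstream conformational sampling is
out of scope here.

The fixture generator (`generate_structure_fixture()`) builds toy
multi-chain models whose side chains are displaced by a known amount — a
synthetic stand-in for conformational-sampling output that forces known
answers (a rigid 1.0 Å displacement must score exactly 1.0 Å after
superposition, because the backbone anchors the fit).

## What the synthetic data do and do not show

The generator reproduces the *structure* of the study's data — stimulus
protocols, sampling, catalog cross-classifications, ensemble scoring — with
controllable ground truth, which is what the test suite needs. It does not
reproduce receptor-specific kinetics (no published rate constants exist),
correlated recording noise, series-resistance or junction artifacts,
single-channel stochasticity, or real conformational sampling. Passing tests
therefore demonstrate that the estimators recover known truth under
idealized conditions, not that any particular receptor behaves like the
defaults.

## Problem sizes used in the checks

The packaged checks run at deliberately modest sizes chosen to exercise the
statistics without waste: 50 seeded replicates for the kinetics and gating
recovery properties, 10,000 null replicates for the Dunnett calibration,
an exhaustive Fisher sweep over all tables with total ≤ 40, and ensembles of
12–20 members with 10 scored. Each is stated where it is used.

## A worked example

```{r, eval = FALSE}
wt <- kinetic_scheme()
variant <- make_variant_scheme(wt, c(beta_open = 0.3, koff = 3))
proto <- stimulus_protocol() # 1 mM GABA, 10 ms pulse, 10 kHz

gw <- fit_gating(simulate_current(wt, proto, noise_sd = 5, seed = 1))
gv <- fit_gating(simulate_current(variant, proto, noise_sd = 5, seed = 2))
gating_impairment_ratio(gv$activation_tau, gw$activation_tau,
                        gv$deactivation_weighted_tau,
                        gw$deactivation_weighted_tau)

cat3 <- gabr_functional_catalog()
fisher_exact_2x2(build_contingency(cat3, polyphen_category == "damaging",
                                   reduced_current))
```

## Known limitations

* The five-state scheme cannot reproduce multi-phasic desensitization or
  subunit-specific pharmacology; it is the minimal scheme for the readouts
  the pipeline measures.
* The exponential fitter's identifiability guard trades resolution of
  closely spaced time constants for robustness against overfitting.
* The LogEC50 change ratio is unit-dependent by construction; the package
  fixes molar units and says so loudly rather than pretending the ratio is
  dimensionless in a unit-free sense.
* Interface-side annotations are static bookkeeping, not computed from
  structures.
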