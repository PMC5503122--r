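---
title: "Data-driven bond-valence parameters for metal coordination sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven bond-valence parameters for metal coordination sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvfit)
```

## The model

The bond-valence model assigns every metal–ligand bond a *valence*
determined by its length,

$$ v_{ij} = \exp\!\left[\frac{R_0 - d_{ij}}{b}\right], $$

and asserts the *sum rule*: the valences of the bonds of a metal center
should add up to its oxidation state,
$V_i = \sum_j v_{ij} \approx S_i$. Here $d_{ij}$ is the bond length in Å,
$b$ is a global softness parameter fixed at 0.37 Å (a standard choice that
works across bond types; `bvfit` exposes it on every parameter set but
never fits it), and $R_0$ is the bond-type-specific length at which a
single bond carries exactly one valence unit. A *bond type* in this
package is a metal species — element, integer oxidation state, and
optionally a spin class — paired with a ligand element, written as a key
like `"Fe2:HS-N"` or `"Na1-O"`.

For a **homoleptic** site (all ligand atoms one element) the sum rule
inverts in closed form,

$$ R_0 = b\left[\ln S_i - \ln \sum_j e^{-d_{ij}/b}\right], $$

which is the classical route to reference parameters: compute per-site
$R_0$ over a curated set of homoleptic complexes and report mean and
standard deviation (`homoleptic_r0()`, `homoleptic_summary()`).
**Heteroleptic** sites mix several unknown $R_0$ values in one sum and
have no closed form; `bvfit`'s central capability is to fit all $R_0$
parameters of one metal species *simultaneously* over homoleptic and
heteroleptic sites by minimising

$$ \sigma^2 = \sum_i (V_i - S_i)^2 $$

with nonlinear conjugate gradients (`fit_r0()`). This typically multiplies
the usable sample size several-fold and reaches bond types that have
essentially no homoleptic representatives.

## Curation

Raw coordination spheres are noisy. `curate_sites()` applies, in order:

* **entry-level exclusions** — disordered structures, crystallographic
  R factor above 7.5% (fraction 0.075; percent-style input is normalised
  on read), and metal sites with any metal–carbon bond (organometallics
  follow different chemistry);
* **oxidation-state assignment** — a three-part cascade
  (`assign_oxidation()`): a clear, unambiguous marker in the compound name
  (`"iron(III)"`, `"ferrous"`); otherwise ligand-template charge balance,
  $S = q_\mathrm{complex} - \sum q_\mathrm{ligand}$, with template matches
  supplied by the caller; otherwise a pluggable mixed-metal hook that
  defaults to *unassigned*. Unassigned and non-integral results exclude
  the site. Bond-valence sums are never consulted, so the assignment
  cannot bias the quantity being fitted;
* **first-sphere trimming** (`first_sphere()`) — a ligand contributing
  less than 5% of $S_i$ under literature reference parameters is outside
  the first coordination sphere. The fractional rule is applied as its
  closed-form distance cutoff
  $d_\mathrm{cutoff} = R_0 - b[\ln 0.05 + \ln S_i]$ (about $R_0 + 0.85$ Å
  for a divalent cation), per ligand, in a single pass. The cutoff form is
  normative: the literal "<5% of the realised total" is self-referential
  once a removal changes the total;
* **site-level rules** (`site_filter()`) — only N, O, F, S, Cl, Br ligands;
  at least two ligands; and the sanity window $V_i \in (0, 2S_i)$, outside
  which a sum indicates a structural error or chemistry the model cannot
  parameterise.

Every input site appears exactly once in the returned ledger with the
stage and reason that removed it; the pipeline is idempotent.

**When the window applies.** The $(0, 2S)$ window can be checked before
fitting with literature values, during fitting with current values, or
both. `bvfit` defaults to *during only* (`fit_r0()` re-checks the window
with the current parameters after each converged pass, prunes violators
and restarts). The reason is concrete: a genuine short-bond low-spin
population scored with *literature* parameters sits at
$S\,e^{\Delta R_0/b}$ — for Fe(II)–N at $2\,e^{0.29/0.37} = 4.4 > 2S$ —
so a literature-first window would deterministically delete the very
population whose discovery motivates the refit, while under its own
fitted parameter the same population is perfectly well behaved.
`filter_config(bvs_window_stage = "before-and-during")` restores the
stricter behaviour for populations where no such split is expected.

## Spin-state splitting

For iron–nitrogen bonds a single $R_0$ leaves a clearly bimodal
distribution of bond-valence sums: low-spin iron has systematically
shorter Fe–N bonds (roughly 1.9–2.1 Å six-coordinate) than high-spin iron
(2.1–2.3 Å), so LS sites score inflated sums under an HS-like parameter.
`split_bimodal()` makes this operational:

1. score every site containing the bond type under the single-parameter
   fit;
2. fit an equal-variance two-component 1-D Gaussian mixture to the sums
   (plain EM, means initialised deterministically at the 25th/75th
   percentiles — no random restarts, so results are seed-independent);
3. hard-assign sites; the *higher*-BVS component is labelled LS;
4. duplicate the bond type into `:LS`/`:HS` keys and refit all parameters
   jointly with assignments fixed;
5. iterate reassignment (each site to the spin class whose parameterisation
   brings its sum closer to $S$) and refitting to a fixed point, capped at
   10 rounds.

If the mixture means are closer than `min_separation` (default 0.3
valence units) no split is declared and the single parameter is retained.
Spin classes attach only to the split bond type: an LS site's Fe–O
contacts still use the plain `Fe2-O` key, and a missing spin-resolved key
is a hard error rather than a silent fallback. The bundled refit
(`reference_params("csd")`) carries Fe(II)–N at 1.57/1.76 Å and
Fe(III)–N at 1.70/1.83 Å for LS/HS; the LS–HS separation mirrors the
known spin-state dependence of ionic radii.

## Uncertainty

Systematic chemical effects (e.g. electron delocalisation) make plain
standard deviations optimistic, so per-type uncertainty is reported as an
upper bound: for each site, $\Delta R_0$ is the shift in *one* parameter
that would make that site obey the sum rule exactly,

$$ \Delta R_0 = b \ln\!\left[1 + \frac{S_i - V_i}{V_\beta}\right], $$

with $V_\beta$ the summed valence of the shifted type's contacts
(reducing to $b\ln(S_i/V_i)$ for homoleptic sites), and the reported
uncertainty is $\sqrt{\operatorname{mean}(\Delta R_0^2)}$ over all sites
containing the type — homoleptic and heteroleptic alike, with infeasible
sites (the logarithm's argument non-positive) skipped and counted. Since
per-site homoleptic $R_0$ equals the fitted value plus $\Delta R_0$,
$\operatorname{RMS}(\Delta R_0)^2 = \operatorname{var}(\Delta R_0) +
\operatorname{mean}(\Delta R_0)^2$ is an identity, and the bound "never
below the spread of per-site $R_0$" holds exactly against the
*population* standard deviation. `homoleptic_summary()` reports the
*sample* (n−1) standard deviation, the usual convention in published
parameter tables, which exceeds the population value by
$\sqrt{n/(n-1)}$ — keep the conventions straight when comparing.

## Typical distances and validation

With a fitted $R_0$, the distance at which $n$ equal contributions sum to
$S$ is $d = R_0 - b\ln(S/n)$ (`typical_distance()`), suitable as a
restraint target in macromolecular refinement. `cmd_validate()` scores
metal sites — read from a site table or extracted from PDB/mmCIF
coordinates within a 4 Å radius — under every candidate oxidation/spin
parameterisation and reports sums, nearest integer states and
$\Delta R_0$ diagnostics.

Two caveats are built into the bundled tables. First, Fe–S parameters
were derived from predominantly tetrahedral sites and are unreliable at
other coordination numbers; the entries carry a CN = 4 validity
annotation that the validator surfaces as a warning. Second, the bundled
*printed* typical-distance table stores, per cell, the effective $S$
under which the published number reproduces: the published iron rows —
including the iron(III) ones — correspond to $S_\mathrm{eff} = 2$ (an
iron(III) LS–N cell of 2.11 Å equals $1.70 + 0.37\ln 3$, which is the
divalent formula; the trivalent formula would give 1.96 Å). Two
tetrahedral Fe–S cells further differ from the recomputed value by
0.01 Å and are flagged `allowlisted`. The self-consistency test
reproduces every other cell to 2 dp.

## The synthetic world

Real parameter derivations run on proprietary curated databases; the
generator (`generate_population()`) emulates the statistical structure
the fit assumes so that every stage is testable:

* coordination numbers drawn from a distribution weighted towards
  octahedral sites (defaults 4:5:6 = 0.2/0.2/0.6);
* a heteroleptic majority (default fraction 0.6, consistent with
  heteroleptic sites dominating fitted sample sizes);
* per-site valence partitions from a symmetric Dirichlet scaled to $S$
  (concentration 20 by default; $\infty$ recovers equal contributions);
* distances $d_{ij} = R_0^{\alpha\beta} - b\ln v_{ij} +
  \mathcal N(0, \sigma_d)$ with $\sigma_d = 0.02$ Å by default, typical
  coordinate precision of well-refined small-molecule structures (noise
  is Gaussian on distances, the simplest model consistent with
  coordinate error);
* optional two-spin Fe–N mixtures (default LS fraction 0.3, a minor LS
  mode) and optional outlier sites whose distances are shortened by
  $b\ln 3$ so their sums land near $3S$, exercising the window pruning;
* clean metadata, and synthetic compound names embedding the oxidation
  state so the name parser resolves it after a site-table round trip.

With zero noise the generator and fitter are exactly consistent
(objective zero at the truth; recovery to $<10^{-6}$ Å), and the same
seed reproduces the population bit-for-bit.

What a green test does **not** establish: the generator draws i.i.d.
sites with exact sum-rule validity and symmetric noise. Real populations
carry correlated errors, Jahn–Teller and other systematic distortions,
charge transfer and delocalisation, heterogeneous refinement quality, and
database covariates (space groups, temperature) that the generator does
not emulate. Recovery on synthetic data validates the estimator and its
implementation, not the chemistry of any particular database.

## Numerical choices

* **Optimiser.** Polak–Ribière+ conjugate gradients with steepest-descent
  restart on non-descent directions; convergence at
  $\max_\beta |\partial\sigma^2/\partial R_0^\beta| \le 10^{-8}$ by
  default. The gradient is analytic:
  $\partial\sigma^2/\partial R_0^\beta = (2/b)\sum_i (V_i - S_i)V_{i\beta}$.
* **Line search.** Derivative-based: expand a bracket until
  $\varphi'(t) = \nabla f(x + t d)\cdot d$ changes sign, then
  secant/bisection on $\varphi'$ until the strong curvature condition
  $|\varphi'(t)| \le 0.1\,|\varphi'(0)|$ holds. Working on the analytic
  derivative matters: near the minimum of a noisy-population objective
  ($\sigma^2 \sim 10^2$), differences of $f$ itself drop below double
  rounding long before the gradient reaches tolerance, and a
  function-value zoom stalls. A stall at the numerical floor counts as
  converged only when $\max|g| \le 10^{-7}\max(1, f)$.
* **Pruning.** Window violators are removed only *between* converged
  passes (at most 20), never mid-line-search, so each pass optimises a
  fixed objective and the trace stays non-increasing; the prune ledger
  records the pass number. Re-running the fit on the kept set reproduces
  the parameters to $<10^{-10}$ Å.
* **Mixture tie-breaks.** EM initialisation at fixed percentiles makes
  the split deterministic; responsibilities of exactly 0.5 go to the
  higher-BVS (LS) component. A collapsed (single-class) reassignment
  round ends the hard-EM loop with the previous assignment.
* **Degenerate inputs.** Empty sites have sum 0 and are rejected by the
  minimum-ligand rule; a bond type losing all sites to pruning, a missing
  parameter key, and a non-positive $\Delta R_0$ logarithm argument are
  all named errors, not silent values.
* **Rounding.** All computation at full precision; report output rounds
  distances and sums to 2 dp and $R_0$ shifts to 3 dp, matching published
  convention. Published worked-example sums reproduce from
  full-precision sums rounded once at the end (one published cell, the
  LS-scored deoxyhemoglobin sum, is itself a sum of rounded cells —
  1.19 printed vs 1.18 recomputed — and is documented rather than
  matched).

## Limitations

* $b$ is fixed, the exponential functional form is the only one
  implemented, and each metal species is fitted independently.
* Ligand-template *matching* (which atoms form a donor group) is the
  caller's responsibility; only the charge balance is computed. The
  bundled table is a 22-entry demonstration, not a general catalog.
* Coordinate-file extraction reads the asymmetric unit only (no
  crystallographic symmetry expansion), excludes hydrogens and other
  metals from contacts, and uses minimal parsers sufficient for
  coordination-sphere extraction — not general-purpose PDB/mmCIF
  readers.
* Mixed-metal oxidation statistics (assignment step iii) are a hook, not
  an implementation.
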