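---
title: "Joint source and health-risk apportionment of speciated PM2.5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint source and health-risk apportionment of speciated PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pmfrisk couples two standard tools of ambient aerosol analysis into one
pipeline: USEPA-style inhalation risk assessment of heavy metals in PM2.5,
and uncertainty-weighted receptor modelling (positive matrix factorization,
PMF). The coupling works by converting per-sample hazard quotients (HQ) and
incremental lifetime cancer risks (ILCR) into concentration-scale
pseudo-species that are appended to the chemical speciation matrix before
factorization, so that every resolved emission source receives not only a
mass share but also a share of the carcinogenic and non-carcinogenic risk.

This vignette is the package's methods reference: the models, their
assumptions, the tunable parameters and the numerical choices, and what the
validation on synthetic campaigns does and does not establish.

## The inhalation risk model

For a metal with ambient concentration $C$ (mg/m^3^), the average daily
inhaled dose is

$$D_\mathrm{inh} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}$$

with population-average defaults $IR = 17.6$ m^3^/d (respiration rate),
$EF = 255$ d/yr (exposure frequency), $ED = 70$ yr (exposure duration),
$BW = 60$ kg (body weight) and $AT = 70 \times 365$ d (averaging time, used
for both carcinogens and non-carcinogens). $ED$ is interpreted in years:
with $EF$ in days per year and $AT$ in days this is the only dimensionally
consistent reading and matches standard USEPA practice. Non-carcinogenic
and carcinogenic risks follow as

$$HQ = D_\mathrm{inh} / RfD, \qquad ILCR = D_\mathrm{inh} \times SF,$$

with reference doses and inhalation slope factors for the four assessed
metals fixed at RfD = 2.86e-5 (Cr), 2.06e-2 (Ni), 3.01e-4 (As), 1.00e-3
(Cd) mg/(kg d) and SF = 42 (Cr), 0.84 (Ni), 15.1 (As), 6.3 (Cd)
(mg/(kg d))^-1^. Two caveats are deliberate and documented:

* The Cr factors are Cr(VI) toxicity values applied to measured *total* Cr
  (the speciation does not resolve oxidation states), so Cr risks are
  upper bounds.
* The package's internal concentration unit is ng/m^3^ and the dose
  equation converts by 1e-9. Published campaign risk totals in this
  literature are sometimes only reproducible if trace-element values are
  fed to the dose equation at µg-scale (a factor-1000 inflation); pmfrisk
  keeps the dimensionally correct conversion. Percentage shares per metal
  are unaffected by any such overall scale, which is why shares — not
  absolute totals — are the robust quantities to compare across studies.

All risk equations are linear in concentration, so the campaign mean of the
per-sample risk equals the risk of the campaign-mean concentration; the test
suite checks this identity to 1e-12 together with hand-computed oracle
values.

## Equivalent conversion to pseudo-species

Raw HQ and ILCR values (typically 1e-6 to 1e-1) are orders of magnitude
below element concentrations, so adding them directly to the factorization
input would make them numerically invisible. The equivalent conversion

$$x_\mathrm{conv} = \frac{10}{-\log_{10} x}, \qquad x \in (0, 1)$$

maps $10^{-k} \mapsto 10/k$, is strictly increasing, and brings both indices
to roughly the scale of trace-element concentrations in ng/m^3^. The log
base is taken as 10; that is what produces the element-scale magnitudes for
risks in the relevant range. Because the formula diverges as $x \to 1$,
inputs at or above 0.99 are clipped to 0.99 (converted value about 2292)
and flagged; hourly HQ values can exceed 1 even when the campaign mean is
safely below it. Non-positive inputs (possible when a metal concentration
is exactly zero) yield a missing value with a flag. The eight converted
series (ILCR and HQ for four metals) are appended to the 18 measured
species, giving the 26-column factorization input.

## The measurement-uncertainty model

Per-cell uncertainties follow the standard receptor-modelling heuristic

$$u_{ij} = \sqrt{DL_j^2 + (CV_j \, x_{ij})^2}$$

where the detection limit is estimated as twice the standard deviation of
the field blanks and $CV_j$ is the analytical coefficient of variation.
Defaults are $CV = 0.1$ for every species and $DL$ equal to 1% of the
species' typical campaign mean — declared assumptions, configurable per
species. Below-DL values are replaced by $DL/2$ with uncertainty
$(5/6)DL$; missing values by the species median with uncertainty
$4 \times$ median; both policies are flagged per cell and configurable.
A floor of 1e-12 keeps every weight finite. The risk pseudo-species inherit
the CV of their parent metal with $DL = 0$: the conversion is monotone, and
a first-order error propagation through the logarithm is deliberately not
attempted; an `inflation` multiplier lets users down-weight the
pseudo-species if they prefer the factorization to be driven by chemistry
alone.

## The receptor model

The factorization minimizes the uncertainty-weighted objective

$$Q = \sum_{ij} \left( \frac{x_{ij} - (GF)_{ij}}{u_{ij}} \right)^2$$

over non-negative contributions $G$ ($n \times K$, ng/m^3^) and profiles
$F$ ($K \times m$). The default solver alternates exact weighted
non-negative least-squares updates: each sweep solves every row of $G$ and
every column of $F$ to optimality with an active-set NNLS on the normal
equations. Each half-step is an exact minimization of its block, so $Q$ is
non-increasing by construction (tested every iteration), and active-set
solutions carry exact zeros — the geometry that tracer-sparse source
profiles actually have. Multiplicative (Lee-Seung) updates with per-cell
weights $1/u^2$ are available as an alternative; they are also monotone but
reach the non-negativity boundary only asymptotically, which in practice
leaves them drifting longer along near-flat rotation directions.

Starts are initialized with absolute values of Gaussian draws scaled to the
data magnitude, sub-seeded per start from the fit seed; the lowest-Q start
wins. Convergence is declared when the relative change in $Q$ stays below
1e-6 for 10 consecutive sweeps (2000 sweep maximum). After fitting, each
profile row is normalized to sum to 1 over the *mass* species (the
pseudo-species are excluded from the normalizer) and the scale is absorbed
into $G$, so factor contributions are mass concentrations.

The expected objective uses the degrees-of-freedom convention
$Q_\mathrm{exp} = nm - K(n + m)$; a well-specified model has
$Q/Q_\mathrm{exp}$ near 1. Factor-number scans fit each $K$ in a range from
several random starts and tabulate $Q/Q_\mathrm{exp}$; the suggested $K$ is
the smallest whose relative drop to $K+1$ falls below 10% (configurable) —
the point where adding a factor stops explaining meaningful variation.

### Rotational ambiguity

Bilinear models admit families of factorizations with nearly identical fit
quality. pmfrisk acknowledges this rather than resolving it: no constrained
rotations are offered, multi-start fitting plus full seed logging provide
reproducibility, and the limitation shapes how recovery is validated (next
section). On the default synthetic campaign the flat region is concentrated
in the allocation of the bulk species (OC, EC, nitrate, sulfate) among
factors; the species-wise *pattern* — which factor dominates which species —
is stable. For this reason `match_factors()` compares profiles
species-relative by default (each species column scaled to unit norm across
factors, the same view as percent-of-species profile displays): that metric
scores the chemically identifying structure instead of being dominated by
bulk-mass allocations whose rotational spread is a known property of PMF,
not an implementation defect. The raw mass-fraction metric remains available
via `scale = "none"`.

## The synthetic campaign generator

The generator produces campaigns with known ground truth matching the
statistical structure the analysis assumes: $K$ latent sources with fixed
tracer-dominated profiles, lognormal autocorrelated contribution series,
and heteroscedastic noise from the uncertainty model itself.

* **Profiles.** Each source is a named set of non-negative tracer weights
  over the species list, normalized to fractions. The default seven-source
  winter mix — secondary (NO3 + SO4), biomass burning (K, Ba), traffic
  (Mn with moderate Cr, Ni, Fe and EC above OC), fugitive dust (Ca, Si,
  Fe), industry (Cd, Si, Hg, plus the largest Cr and substantial As), coal
  combustion (As, Pb, OC, EC) and heavy-oil combustion (V, Ni) — is frozen
  in the package. Species a source does not emit are true zeros: the
  generator emulates well-separated, tracer-dominated profiles, because
  that is the regime in which factorization recovery is meaningful to test
  (with dense all-positive profiles the factorization is rotationally
  unidentifiable and no recovery statement would be falsifiable). Totals
  were chosen so that secondary sources carry roughly 60% of the mass,
  industry is a minor mass source that nevertheless dominates the toxic
  metals, element means follow the Fe > Si > Ca ordering, and the four risk
  metals give a Cr-dominated ILCR and HQ.
* **Contributions.** Each factor's series is an exponentiated Gaussian
  AR(1): $g_t = \mu \exp(\sigma z_t - \sigma^2/2)$ with $z_t$ a stationary
  standard-normal AR(1). Defaults $\phi = 0.9$ (hourly persistence) and
  $\sigma = 0.8$ give lognormal marginals with episodic pollution peaks and
  stationary mean $\mu$. With $\sigma = 0$ the series is constant — the
  degenerate case the tests use.
* **Noise.** $x_{ij} = (G F)_{ij} + \varepsilon_{ij}$ with
  $\varepsilon_{ij} \sim N(0, u_{ij})$, $u$ evaluated at the noiseless
  value. Negative draws are truncated to zero and counted, mirroring how
  instruments report; under the defaults the truncation fraction is well
  below 1%.
* **Seeding.** All randomness flows from one campaign seed through
  documented sub-seeds per stage (contributions, noise, blanks,
  missingness), so campaigns are bit-reproducible.
* **Risk pseudo-species.** Two modes exist. By default the campaign has
  the 18 measured species and risk indices are computed downstream with
  `risk_series()`, exactly as on real data. With
  `include_risk_truth = TRUE` the eight converted indices are instead part
  of the bilinear truth: each metal's pseudo-species is allocated across
  sources in proportion to that metal's emissions and scaled to the
  magnitude the conversion would produce. Only the second mode carries a
  ground-truth *risk attribution*, so it is the one the risk-apportionment
  stage is validated against. The distinction matters: when the
  pseudo-species are downstream concave (log-scale) transforms, their
  per-factor allocation in a joint bilinear fit is ill-conditioned — the
  compressed series are dominated by a baseline that the fit can assign to
  any sufficiently smooth factor combination at essentially no cost in Q.
  Risk shares computed from such a fit reflect that arbitrariness, not the
  true origin of the metals; this is a structural property of embedding
  nonlinear indices in a bilinear model, documented here so users do not
  over-interpret risk shares from the downstream mode.

What the generator does *not* emulate: meteorological covariates, secondary
chemistry (secondary formation is just a latent factor), instrument drift,
or any structured missingness pattern (an optional missing-at-random
fraction is provided, with no claim of realism). Passing recovery tests on
this generator therefore demonstrates that the pipeline is statistically
consistent under its own assumptions — not that any particular field
campaign satisfies those assumptions.

## Apportionment and labelling

Explained variation allocates each species' modelled mass across factors:
$\mathrm{EV}_{kj} = \sum_i G_{ik} F_{kj} / \sum_{i,k'} G_{ik'} F_{k'j}$.
Tracer rules label factors: a rule names required high-loading species
(the factor must be the EV argmax for each and hold at least 40% — both
configurable), optional moderate species, and optional auxiliary predicates
such as EC exceeding OC for traffic. Rules apply greedily by specificity;
conflicting claims resolve toward the higher summed share with a warning,
and unmatched factors stay "unassigned". Labelling is permutation-invariant
by construction.

Mass shares are factor column sums of $G$ over total modelled mass
(normalized over *modelled*, not measured, mass). Risk shares apportion
each converted pseudo-species across factors by explained variation and
then aggregate the four metals weighted by each metal's campaign-mean
*original* (unconverted) ILCR or HQ: converted values are not additive in
risk space, so aggregation happens on the risk scale. This aggregation rule
is recorded in the output's metadata since other conventions are
conceivable. The lifetime-risk index — the per-sample sum of all eight
converted indices — provides a concentration-scale time series of
metal-borne hazard.

## Problem sizes and numerical choices

The validation campaign uses the full study dimensions: 2622 hourly samples,
18 measured species plus 8 pseudo-species, 7 sources, CV = 0.1, 10 random
starts per fit. Unit tests run on miniature campaigns (3 sources, 8 species,
a few hundred samples) where brute-force oracles are feasible: the weighted
uncertainty matrix is compared cell-by-cell against direct recomputation,
and tiny factorizations (20 x 4) are checked against a box-constrained
quasi-Newton minimizer restarted 500 times — an optimizer sharing no code
with the package's solvers. Factor-number scans in tests use the miniature
campaign (true K = 3) and recover the elbow at 3; the full 1-10 scan is
exercised by the acceptance script with the cheaper multiplicative solver.

Degenerate inputs are handled explicitly: zero uncertainties are floored,
zero-variance inputs to the fit diagnostics raise errors, profile rows that
are entirely zero are left unnormalized, and conversion of out-of-domain
risk values is clipped or set missing with flags rather than propagating
infinities.

## Known limitations

* Rotational ambiguity bounds what profile recovery can promise (see
  above); bulk-species allocations between chemically similar sources
  (e.g. two OC-rich combustion factors) carry real uncertainty that the
  best-fit Q cannot resolve.
* The bilinear model can only approximate the pseudo-species, which are
  nonlinear (log-scale) transforms of metal concentrations; their residuals
  are structurally larger than the chemistry's.
* Inhalation is the only exposure pathway; no age or gender stratification.
* The elbow rule for factor-number selection is a heuristic; the scan table
  should be inspected, not consumed blindly.
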