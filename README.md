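# pmfrisk

Joint source apportionment and inhalation health-risk allocation for
speciated PM2.5.

Urban and suburban PM2.5 is a mixture from distinct emission sources —
secondary aerosol, biomass burning, traffic, dust, industry, coal and
heavy-oil combustion — and its toxic heavy metals (Cr, Ni, As, Cd) are not
emitted in proportion to mass. A source contributing a few percent of the
mass can carry most of the carcinogenic risk. pmfrisk quantifies both sides
of that picture from one hourly speciation table: it computes USEPA-style
inhalation risk per sample and metal, resolves emission sources by
uncertainty-weighted positive matrix factorization (PMF), and — by entering
converted risk indices into the factorization as pseudo-species — allocates
the health risk itself across the resolved sources.

The package is written for air-quality and exposure scientists working with
hourly speciated campaigns (carbon fractions, water-soluble ions, trace
elements).

## The models in brief

Inhalation dose for a metal at concentration C (mg/m³):

    Dinh = C · IR · EF · ED / (BW · AT)        [mg/(kg·d)]
    HQ   = Dinh / RfD                          (non-carcinogenic)
    ILCR = Dinh · SF                           (carcinogenic)

with population-average exposure defaults (IR 17.6 m³/d, EF 255 d/yr,
ED 70 yr, BW 60 kg, AT 70×365 d) and USEPA toxicity factors for Cr, Ni, As,
Cd. Risk indices are mapped to concentration scale by the equivalent
conversion `x → 10 / (−log10 x)` so they can join the speciation matrix.

The receptor model minimizes the uncertainty-weighted objective

    Q = Σ_ij ( (x_ij − (G F)_ij) / u_ij )²,   G ≥ 0, F ≥ 0

with per-cell uncertainties `u_ij = sqrt(DL_j² + (CV_j x_ij)²)` (detection
limits from field blanks, DL = 2 × blank SD). The solver is an alternating
exact weighted non-negative least squares (active-set NNLS per row/column;
monotone in Q), with multi-start initialization and `Q/Qexp` factor-number
scans (`Qexp = nm − K(n+m)`). Factors are labelled as sources by tracer
rules on explained variation, and mass shares, ILCR shares and HQ shares
per source are reported. A seeded synthetic-campaign generator with known
profiles, contributions and noise structure backs the test suite.

## Worked example

Simulate a 500-hour campaign from the default seven-source winter mix,
assess the metal risks, fit the factorization and apportion the mass:

```r
library(pmfrisk)

sim <- simulate_campaign(n_samples = 500, seed = 42)
risk_summary(sim$data)
#>   metal mean_conc_ngm3     dinh           hq     ilcr hq_share_pct ilcr_share_pct
#> 1 Cr              6.66 1.36e- 9 0.0000477    5.73e- 8      87.9            64.6
#> 2 Ni              2.08 4.26e-10 0.0000000207 3.58e-10       0.0381          0.404
#> 3 As              8.61 1.77e- 9 0.00000586   2.67e- 8      10.8            30.1
#> 4 Cd              3.35 6.87e-10 0.000000687  4.33e- 9       1.27            4.88
```

Chromium dominates both the non-carcinogenic hazard (87.9% of the summed
HQ) and the cancer risk (64.6% of the summed ILCR); every campaign-mean
index sits below its USEPA threshold (`hq_flag`, `ilcr_band`).

```r
u   <- uncertainty_matrix(sim$data, uncertainty_spec_default())
fit <- pmf_fit(sim$data, u, k = 7, seed = 42, n_starts = 5)
fit
#> <pmf_fit> 7 factors, 500 x 18 matrix
#>   Q = 5363, Qexp = 5374, Q/Qexp = 0.998
#>   converged after 217 iterations (start 1 of 5, seed 42)

mass_shares(fit, label_factors(fit))
#>   factor   source              mass share_pct
#> 1 factor_1 fugitive_dust     782786.      4.50
#> 2 factor_2 heavy_oil         497946.      2.86
#> 3 factor_3 biomass_burning  1131850.      6.51
#> 4 factor_4 industry          662472.      3.81
#> 5 factor_5 traffic          1672146.      9.61
#> 6 factor_6 coal_combustion  2516239.     14.5
#> 7 factor_7 secondary       10133308.     58.2

model_fit_stats(sim$data, fit)
#>   slope intercept r_squared n_cells
#> 1 0.984      8.88     0.993    9000
```

`Q/Qexp = 0.998` says the uncertainty model matches the residual scale; all
seven tracer rules resolve, with secondary aerosol carrying 58% of the
modelled mass; the reconstruction tracks the input cell-by-cell (slope
0.98, R² 0.99). `tidy(fit)`, `glance(fit)`, `autoplot(fit)` and
`plot_contributions(fit)` expose profiles, fit summaries and time series;
`risk_shares()` on a fit that includes the converted risk pseudo-species
allocates ILCR and HQ across the same sources.

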