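#' USEPA inhalation exposure parameters
#'
#' Population-average defaults: respiration rate IR = 17.6 m3/d, exposure
#' frequency EF = 255 d/yr, exposure duration ED = 70 yr, body weight
#' BW = 60 kg, averaging time AT = 70 x 365 d (used for both carcinogens and
#' non-carcinogens). ED is in years: with EF in d/yr and AT in days this is
#' the only dimensionally consistent reading.
#'
#' @param IR,EF,ED,BW,AT Override any parameter; all must be > 0.
#' @return A named list of exposure parameters.
#' @export
exposure_defaults <- function(IR = 17.6, EF = 255, ED = 70, BW = 60,
                              AT = 70 * 365) {
  p <- list(IR = IR, EF = EF, ED = ED, BW = BW, AT = AT)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 TRUE))) {
    abort("all exposure parameters must be positive scalars")
  }
  if (p$AT < p$EF * p$ED / 365) {
    abort("averaging time AT (days) must cover EF * ED")
  }
  p
}

#' Inhalation toxicity table for the four risk metals
#'
#' Reference doses RfD (mg/(kg*d)) and cancer slope factors SF
#' ((mg/(kg*d))^-1) for Cr, Ni, As and Cd. The Cr values are Cr(VI) factors
#' applied to measured total Cr, since the measurements do not speciate
#' chromium; risks for Cr are therefore upper-bound estimates.
#'
#' @return A tibble with columns `metal`, `rfd`, `sf`.
#' @export
toxicity_defaults <- function() {
  tibble::tribble(
    ~metal, ~rfd,      ~sf,
    "Cr",   2.86e-5,   42,
    "Ni",   2.06e-2,   0.84,
    "As",   3.01e-4,   15.1,
    "Cd",   1.00e-3,   6.3
  )
}

#' Risk metals assessed by default
#' @return Character vector `c("Cr","Ni","As","Cd")`.
#' @export
risk_metals_default <- function() toxicity_defaults()$metal

#' Assemble and validate a campaign configuration
#'
#' Fills defaults for any block not supplied and checks the invariants:
#' a factor-number range within `[1, 10]`-style bounds, at least one random
#' start, a toxicity entry for every requested risk metal, and an
#' uncertainty entry (DL + CV) for every mass species.
#'
#' @param exposure Named list as from [exposure_defaults()].
#' @param toxicity Tibble as from [toxicity_defaults()].
#' @param uncertainty Tibble as from [uncertainty_spec_default()].
#' @param factor_range Integer pair `c(k_min, k_max)`.
#' @param n_starts Number of random starts per factor count.
#' @param seed Campaign seed (single integer).
#' @param mass_species Species counted as mass (risk pseudo-species excluded).
#' @param risk_metals Metals entering the risk assessment.
#' @return A validated `campaign_config` list.
#' @export
campaign_config <- function(exposure = exposure_defaults(),
                            toxicity = toxicity_defaults(),
                            uncertainty = uncertainty_spec_default(),
                            factor_range = c(1L, 10L),
                            n_starts = 10L,
                            seed = 1L,
                            mass_species = mass_species_default(),
                            risk_metals = risk_metals_default()) {
  cfg <- list(exposure = exposure, toxicity = toxicity,
              uncertainty = uncertainty, factor_range = as.integer(factor_range),
              n_starts = as.integer(n_starts), seed = as.integer(seed),
              mass_species = mass_species, risk_metals = risk_metals)
  class(cfg) <- "campaign_config"
  validate_campaign_config(cfg)
}

#' Validate a campaign configuration
#'
#' @param config A `campaign_config` list.
#' @return The checked config, invisibly identical to the input.
#' @export
validate_campaign_config <- function(config) {
  fr <- config$factor_range
  if (length(fr) != 2 || fr[1] < 1 || fr[2] < fr[1]) {
    abort("factor_range must be an increasing pair with k_min >= 1")
  }
  if (config$n_starts < 1) abort("n_starts must be >= 1")
  exposure_defaults(IR = config$exposure$IR, EF = config$exposure$EF,
                    ED = config$exposure$ED, BW = config$exposure$BW,
                    AT = config$exposure$AT)
  missing_tox <- setdiff(config$risk_metals, config$toxicity$metal)
  if (length(missing_tox)) {
    abort(sprintf("missing toxicity entry for metal(s): %s",
                  paste(missing_tox, collapse = ", ")))
  }
  if (any(config$toxicity$rfd <= 0)) abort("RfD must be > 0")
  if (any(config$toxicity$sf < 0)) abort("SF must be >= 0")
  missing_unc <- setdiff(config$mass_species, config$uncertainty$species)
  if (length(missing_unc)) {
    abort(sprintf("uncertainty spec missing species: %s",
                  paste(missing_unc, collapse = ", ")))
  }
  invisible(config)
}
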