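#' Average daily inhaled dose
#'
#' Dinh = C * IR * EF * ED / (BW * AT), the USEPA inhalation exposure dose in
#' mg/(kg*d). Linear in concentration.
#'
#' @param conc_mg_m3 Concentration(s) in mg/m3, >= 0.
#' @param params Exposure parameters, see [exposure_defaults()].
#' @return Dose(s) in mg/(kg*d), same length as `conc_mg_m3`.
#' @export
daily_dose <- function(conc_mg_m3, params = exposure_defaults()) {
  if (any(conc_mg_m3 < 0, na.rm = TRUE)) abort("concentration must be >= 0")
  conc_mg_m3 * params$IR * params$EF * params$ED / (params$BW * params$AT)
}

#' Non-carcinogenic hazard quotient
#'
#' HQ = Dinh / RfD. HQ < 1 indicates negligible non-carcinogenic risk.
#'
#' @param dinh Dose in mg/(kg*d).
#' @param rfd Reference dose in mg/(kg*d), > 0.
#' @return Hazard quotient(s), unitless.
#' @export
hazard_quotient <- function(dinh, rfd) {
  if (any(rfd <= 0)) abort("RfD must be > 0")
  dinh / rfd
}

#' Incremental lifetime cancer risk
#'
#' ILCR = Dinh * SF.
#'
#' @param dinh Dose in mg/(kg*d).
#' @param sf Cancer slope factor in (mg/(kg*d))^-1, >= 0.
#' @return ILCR probability(ies), unitless.
#' @export
cancer_risk <- function(dinh, sf) {
  if (any(sf < 0)) abort("SF must be >= 0")
  dinh * sf
}

#' Classify an ILCR value against the USEPA thresholds
#'
#' Three-level flag: below the 1e-6 safe threshold, within the 1e-6 to 1e-4
#' acceptable band, or above 1e-4.
#'
#' @param ilcr ILCR value(s).
#' @return Character vector: `"below_safe"`, `"acceptable"`, `"above_limit"`.
#' @export
ilcr_band <- function(ilcr) {
  dplyr::case_when(
    ilcr < 1e-6 ~ "below_safe",
    ilcr <= 1e-4 ~ "acceptable",
    TRUE ~ "above_limit"
  )
}

#' Equivalent conversion of a risk index to concentration scale
#'
#' Maps a risk index x in (0, 1) to `10 / (-log10(x))`, so that 10^-k maps to
#' 10/k. The conversion is strictly increasing on its domain and brings HQ
#' and ILCR values (typically 1e-6 to 1e-1) to the same magnitude as trace
#' element concentrations in ng/m3, which is what allows them to enter the
#' factorization as pseudo-species.
#'
#' Values at or above `clip_hi` (where the formula diverges as x -> 1) are
#' clipped and flagged; non-positive or vanishingly small values give NA with
#' a flag.
#'
#' @param x Risk index value(s) (HQ or ILCR).
#' @param clip_hi Upper clip threshold, default 0.99.
#' @param tiny Values <= `tiny` are treated as effectively zero (NA result).
#' @return Numeric vector of converted indices, with attribute `flag`
#'   (`"ok"`, `"clipped"`, `"nonpositive"`).
#' @export
convert_risk_index <- function(x, clip_hi = 0.99, tiny = 1e-30) {
  flag <- rep("ok", length(x))
  flag[!is.na(x) & x <= tiny] <- "nonpositive"
  flag[!is.na(x) & x >= clip_hi] <- "clipped"
  xx <- pmin(x, clip_hi)
  out <- 10 / (-log10(xx))
  out[flag == "nonpositive"] <- NA_real_
  attr(out, "flag") <- flag
  out
}

risk_species_names <- function(metals = risk_metals_default()) {
  c(paste0("ILCRc_", metals), paste0("HQc_", metals))
}

#' Per-sample health-risk series for the risk metals
#'
#' Computes, for every sample and metal, the inhaled dose, HQ, ILCR and
#' their equivalent-converted values. Concentrations are taken from the
#' species table in ng/m3 and converted to mg/m3 (x 1e-9) inside the dose
#' equation.
#'
#' @param data Species table (ng/m3) containing all `metals`.
#' @param metals Metals to assess; default Cr, Ni, As, Cd.
#' @param params Exposure parameters.
#' @param tox Toxicity table with `metal`, `rfd`, `sf`.
#' @return A long tibble: `timestamp`, `metal`, `conc_ngm3`, `dinh`, `hq`,
#'   `ilcr`, `hq_conv`, `ilcr_conv`, `flag_hq`, `flag_ilcr`.
#' @export
risk_series <- function(data, metals = risk_metals_default(),
                        params = exposure_defaults(),
                        tox = toxicity_defaults()) {
  missing <- setdiff(metals, names(data))
  if (length(missing)) {
    abort(sprintf("metal(s) absent from table: %s",
                  paste(missing, collapse = ", ")))
  }
  missing_tox <- setdiff(metals, tox$metal)
  if (length(missing_tox)) {
    abort(sprintf("missing toxicity entry for: %s",
                  paste(missing_tox, collapse = ", ")))
  }

  long <- data |>
    dplyr::select(dplyr::all_of(c("timestamp", metals))) |>
    tidyr::pivot_longer(dplyr::all_of(metals), names_to = "metal",
                        values_to = "conc_ngm3") |>
    dplyr::left_join(tox, by = "metal") |>
    dplyr::mutate(
      dinh = daily_dose(.data$conc_ngm3 * 1e-9, params),
      hq = hazard_quotient(.data$dinh, .data$rfd),
      ilcr = cancer_risk(.data$dinh, .data$sf)
    )
  hc <- convert_risk_index(long$hq)
  ic <- convert_risk_index(long$ilcr)
  long$hq_conv <- as.numeric(hc)
  long$flag_hq <- attr(hc, "flag")
  long$ilcr_conv <- as.numeric(ic)
  long$flag_ilcr <- attr(ic, "flag")
  long |>
    dplyr::select(dplyr::all_of(c("timestamp", "metal", "conc_ngm3", "dinh",
                                  "hq", "ilcr", "hq_conv", "ilcr_conv",
                                  "flag_hq", "flag_ilcr")))
}

#' Append converted risk indices to a species table as pseudo-species
#'
#' Adds the 2 x length(metals) converted columns (`ILCRc_<metal>`,
#' `HQc_<metal>`) so an 18-species table becomes the 26-column factorization
#' input.
#'
#' @param data Species table.
#' @param risk Output of [risk_series()] on the same table.
#' @return The widened species table.
#' @export
append_risk_species <- function(data, risk) {
  metals <- unique(risk$metal)
  wide_ilcr <- risk |>
    dplyr::select(dplyr::all_of(c("timestamp", "metal", "ilcr_conv"))) |>
    tidyr::pivot_wider(names_from = "metal", values_from = "ilcr_conv",
                       names_prefix = "ILCRc_")
  wide_hq <- risk |>
    dplyr::select(dplyr::all_of(c("timestamp", "metal", "hq_conv"))) |>
    tidyr::pivot_wider(names_from = "metal", values_from = "hq_conv",
                       names_prefix = "HQc_")
  data |>
    dplyr::left_join(wide_ilcr, by = "timestamp") |>
    dplyr::left_join(wide_hq, by = "timestamp")
}

#' Campaign-level health-risk summary
#'
#' Campaign-mean dose, HQ and ILCR per metal (computed on mean
#' concentrations; identical to the mean of per-sample values because the
#' risk equations are linear), percentage shares of the totals, and
#' threshold flags.
#'
#' @inheritParams risk_series
#' @return A tibble with one row per metal: `metal`, `mean_conc_ngm3`,
#'   `dinh`, `hq`, `ilcr`, `hq_share_pct`, `ilcr_share_pct`, `hq_flag`,
#'   `ilcr_band`. Totals are attached as attribute `totals`
#'   (list `total_hq`, `total_ilcr`).
#' @export
risk_summary <- function(data, metals = risk_metals_default(),
                         params = exposure_defaults(),
                         tox = toxicity_defaults()) {
  rs <- risk_series(data, metals, params, tox)
  out <- rs |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(mean_conc_ngm3 = mean(.data$conc_ngm3, na.rm = TRUE),
                     dinh = mean(.data$dinh, na.rm = TRUE),
                     hq = mean(.data$hq, na.rm = TRUE),
                     ilcr = mean(.data$ilcr, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(
      hq_share_pct = 100 * .data$hq / sum(.data$hq),
      ilcr_share_pct = 100 * .data$ilcr / sum(.data$ilcr),
      hq_flag = ifelse(.data$hq < 1, "negligible", "potential_effect"),
      ilcr_band = ilcr_band(.data$ilcr)
    ) |>
    dplyr::arrange(match(.data$metal, metals))
  attr(out, "totals") <- list(total_hq = sum(out$hq),
                              total_ilcr = sum(out$ilcr))
  out
}

#' Lifetime-risk index series
#'
#' The per-sample sum of the eight equivalent-converted indices (HQ_conv +
#' ILCR_conv over the four metals); an intuitive concentration-scale tracker
#' of metal-borne health hazard through time.
#'
#' @param risk Output of [risk_series()].
#' @return A tibble `timestamp`, `lifetime_index`.
#' @export
lifetime_risk_index <- function(risk) {
  risk |>
    dplyr::group_by(.data$timestamp) |>
    dplyr::summarise(
      lifetime_index = sum(.data$hq_conv, na.rm = TRUE) +
        sum(.data$ilcr_conv, na.rm = TRUE),
      .groups = "drop")
}
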