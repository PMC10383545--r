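#' Detection limits from field blanks
#'
#' DL_j = 2 x sample standard deviation of the field-blank series for
#' species j.
#'
#' @param blanks A tibble of blank measurements, one column per species
#'   (a `timestamp` column, if present, is ignored); at least two blanks per
#'   species.
#' @return A tibble `species`, `dl`.
#' @export
detection_limit_from_blanks <- function(blanks) {
  b <- blanks[setdiff(names(blanks), "timestamp")]
  if (nrow(b) < 2) abort("need at least 2 blanks to define a standard deviation")
  tibble::tibble(species = names(b),
                 dl = unname(2 * vapply(b, stats::sd, 0)))
}

#' Default uncertainty specification
#'
#' One row per measured species with its detection limit (DL, ng/m3) and
#' coefficient of variation (CV, unitless). The default DL is 1% of the
#' species' typical campaign mean and the default CV is 0.1 for every
#' species — a declared assumption, not a reconstruction of any specific
#' instrument.
#'
#' @param cv Scalar CV applied to every species.
#' @param dl_frac DL as a fraction of the typical species mean.
#' @return A tibble `species`, `dl`, `cv`.
#' @export
uncertainty_spec_default <- function(cv = 0.1, dl_frac = 0.01) {
  pm25_species() |>
    dplyr::transmute(species = .data$species,
                     dl = dl_frac * .data$typical_ngm3,
                     cv = cv)
}

#' Extend an uncertainty spec to the converted risk pseudo-species
#'
#' The pseudo-species inherit the CV of their parent metal (scaled by an
#' optional inflation factor that lets users down-weight them) and DL = 0:
#' the conversion is monotone, so a proportional error model is retained
#' rather than attempting a first-order propagation through the log.
#'
#' @param spec Uncertainty spec covering the parent metals.
#' @param metals Risk metals.
#' @param inflation Multiplier on the pseudo-species CV, default 1.
#' @return The spec with 2 x length(metals) extra rows.
#' @export
uncertainty_spec_risk <- function(spec, metals = risk_metals_default(),
                                  inflation = 1) {
  parent <- spec |> dplyr::filter(.data$species %in% metals)
  missing <- setdiff(metals, parent$species)
  if (length(missing)) {
    abort(sprintf("spec lacks parent metal(s): %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- dplyr::bind_rows(
    parent |> dplyr::mutate(species = paste0("ILCRc_", .data$species)),
    parent |> dplyr::mutate(species = paste0("HQc_", .data$species))
  ) |>
    dplyr::mutate(dl = 0, cv = .data$cv * inflation)
  dplyr::bind_rows(spec, extra)
}

#' Per-cell measurement uncertainty matrix
#'
#' u_ij = sqrt(DL_j^2 + (CV_j * x_ij)^2) for every observed cell, floored at
#' a strictly positive minimum (1e-12 ng/m3) so the weighted least-squares
#' objective is always defined.
#'
#' @param data Species table (ng/m3); may include pseudo-species.
#' @param spec Uncertainty spec covering every non-timestamp column.
#' @param floor Positive lower bound on u_ij.
#' @return A numeric matrix (samples x species) of uncertainties.
#' @export
uncertainty_matrix <- function(data, spec, floor = 1e-12) {
  sp <- setdiff(names(data), "timestamp")
  missing <- setdiff(sp, spec$species)
  if (length(missing)) {
    abort(sprintf("no DL/CV for species: %s", paste(missing, collapse = ", ")))
  }
  x <- species_matrix(data)
  dl <- spec$dl[match(sp, spec$species)]
  cv <- spec$cv[match(sp, spec$species)]
  u <- sqrt(matrix(dl^2, nrow(x), ncol(x), byrow = TRUE) +
              sweep(x, 2, cv, `*`)^2)
  pmax(u, floor)
}

#' Apply below-detection-limit and missing-value policies
#'
#' Standard receptor-modelling practice: values below DL are replaced by
#' DL/2 with uncertainty (5/6) DL; missing values are replaced by the species
#' median with uncertainty 4 x median. Every replacement is flagged.
#'
#' @param data Species table (measured species only).
#' @param spec Uncertainty spec covering all species.
#' @param below_dl_value,below_dl_unc Functions of DL giving the replacement
#'   value and uncertainty for below-DL cells.
#' @param missing_unc_factor Multiplier on the species median for the
#'   uncertainty of replaced missing cells.
#' @return A list: `data` (adjusted table), `uncertainty` (matrix with
#'   policy overrides applied), `flags` (tibble `row`, `species`, `flag`
#'   of all replacements).
#' @export
apply_missing_policy <- function(data, spec,
                                 below_dl_value = function(dl) dl / 2,
                                 below_dl_unc = function(dl) 5 / 6 * dl,
                                 missing_unc_factor = 4) {
  sp <- setdiff(names(data), "timestamp")
  x <- species_matrix(data)
  dl <- spec$dl[match(sp, spec$species)]
  if (anyNA(dl)) {
    abort(sprintf("no DL for species: %s",
                  paste(sp[is.na(dl)], collapse = ", ")))
  }

  flags <- list()
  u_override <- matrix(NA_real_, nrow(x), ncol(x))

  for (j in seq_along(sp)) {
    col <- x[, j]
    if (all(is.na(col))) {
      abort(sprintf("species '%s' is entirely missing", sp[j]))
    }
    miss <- which(is.na(col))
    if (length(miss)) {
      med <- median(col, na.rm = TRUE)
      x[miss, j] <- med
      u_override[miss, j] <- missing_unc_factor * med
      flags[[length(flags) + 1]] <- tibble::tibble(
        row = miss, species = sp[j], flag = "missing_replaced")
    }
    below <- which(!is.na(col) & col < dl[j])
    below <- setdiff(below, miss)
    if (length(below)) {
      x[below, j] <- below_dl_value(dl[j])
      u_override[below, j] <- below_dl_unc(dl[j])
      flags[[length(flags) + 1]] <- tibble::tibble(
        row = below, species = sp[j], flag = "below_dl")
    }
  }

  adj <- data
  adj[sp] <- as_tibble(x)
  u <- uncertainty_matrix(adj, spec)
  u[!is.na(u_override)] <- u_override[!is.na(u_override)]
  u <- pmax(u, 1e-12)

  list(data = adj, uncertainty = u,
       flags = if (length(flags)) dplyr::bind_rows(flags) else
         tibble::tibble(row = integer(), species = character(),
                        flag = character()))
}
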