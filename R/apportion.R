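#' Explained variation of species across factors
#'
#' For species j, factor k's share is
#' `sum_i G_ik F_kj / sum_i sum_k' G_ik' F_k'j` — the fraction of the
#' species' modelled mass carried by that factor. Shares sum to 1 per
#' species.
#'
#' @param model A `pmf_fit`.
#' @return A tibble: `species`, `factor`, `share`.
#' @export
explained_variation <- function(model) {
  gsum <- colSums(model$G)
  contrib <- gsum * model$F            # K x m: factor mass per species
  tot <- colSums(contrib)
  tot[tot == 0] <- 1
  share <- sweep(contrib, 2, tot, `/`)
  as_tibble(share, rownames = "factor") |>
    tidyr::pivot_longer(-"factor", names_to = "species", values_to = "share")
}

#' Define a tracer rule for factor labelling
#'
#' @param source Source name assigned when the rule matches.
#' @param required Species the factor must dominate (argmax explained
#'   variation across factors, above the high-loading threshold).
#' @param moderate Species typically present at moderate loading
#'   (documentation only; not enforced).
#' @param aux Optional predicate `function(profile_row)` returning TRUE for
#'   an auxiliary check on the profile (e.g. EC exceeding OC).
#' @return A `tracer_rule` list.
#' @export
tracer_rule <- function(source, required, moderate = character(), aux = NULL) {
  if (!length(required)) abort("a tracer rule needs at least one required species")
  structure(list(source = source, required = required, moderate = moderate,
                 aux = aux), class = "tracer_rule")
}

#' Default tracer rules for the seven winter sources
#'
#' Secondary (NO3 + SO4), biomass burning (K, with Ba), traffic (Mn, with
#' Cr/Ni/Fe; its true profile also has EC above OC, but bulk-carbon
#' allocations are rotationally uncertain, so no EC/OC predicate is imposed
#' by default), fugitive dust (Ca, with Si/Fe/Ba), industry (Cd,
#' with Si/Hg; in this source mix industry also carries the largest Cr
#' emissions), coal combustion (As, with Pb), heavy-oil combustion (V,
#' with Ni).
#'
#' @return A list of [tracer_rule()]s.
#' @export
default_tracer_rules <- function() {
  list(
    tracer_rule("secondary", c("NO3", "SO4")),
    tracer_rule("biomass_burning", "K", moderate = "Ba"),
    tracer_rule("traffic", "Mn", moderate = c("Cr", "Ni", "Fe")),
    tracer_rule("fugitive_dust", "Ca", moderate = c("Si", "Fe", "Ba")),
    tracer_rule("industry", "Cd", moderate = c("Si", "Hg")),
    tracer_rule("coal_combustion", "As", moderate = "Pb"),
    tracer_rule("heavy_oil", "V", moderate = "Ni")
  )
}

#' Label factors as sources via tracer rules
#'
#' A rule matches the factor that is the argmax of explained variation for
#' every one of its required species and holds at least `ev_threshold` of
#' each ("high loading"). Rules are applied greedily by specificity (more
#' required species first); if two rules claim the same factor the one with
#' the higher summed share wins and a warning is raised. Unmatched factors
#' are labelled `"unassigned"`.
#'
#' @param model A `pmf_fit`.
#' @param rules List of [tracer_rule()]s.
#' @param ev_threshold High-loading threshold on explained variation.
#' @return A tibble: `factor`, `source`, `score` (summed required-species
#'   share, NA for unassigned).
#' @export
label_factors <- function(model, rules = default_tracer_rules(),
                          ev_threshold = 0.4) {
  ev <- explained_variation(model) |>
    tidyr::pivot_wider(names_from = "species", values_from = "share")
  factors <- ev$factor
  evm <- as.matrix(ev[-1])
  rownames(evm) <- factors

  labels <- setNames(rep("unassigned", length(factors)), factors)
  scores <- setNames(rep(NA_real_, length(factors)), factors)

  if (length(rules)) {
    spec_order <- order(-purrr::map_int(rules, ~ length(.x$required)))
    candidates <- purrr::map(rules[spec_order], function(r) {
      missing <- setdiff(r$required, colnames(evm))
      if (length(missing)) {
        abort(sprintf("rule '%s' requires unknown species: %s", r$source,
                      paste(missing, collapse = ", ")))
      }
      sub <- evm[, r$required, drop = FALSE]
      argmax_ok <- apply(sub, 2, which.max)
      if (length(unique(argmax_ok)) != 1) return(NULL)
      f <- unique(argmax_ok)
      if (any(sub[f, ] < ev_threshold)) return(NULL)
      if (!is.null(r$aux) && !isTRUE(r$aux(model$F[f, ]))) return(NULL)
      list(source = r$source, factor = factors[f], score = sum(sub[f, ]))
    })
    for (cand in candidates) {
      if (is.null(cand)) next
      f <- cand$factor
      if (labels[f] != "unassigned") {
        if (!is.na(scores[f]) && cand$score > scores[f]) {
          warn(sprintf("factor %s claimed by both '%s' and '%s'; keeping '%s'",
                       f, labels[f], cand$source, cand$source))
          labels[f] <- cand$source
          scores[f] <- cand$score
        } else {
          warn(sprintf("factor %s claimed by both '%s' and '%s'; keeping '%s'",
                       f, labels[f], cand$source, labels[f]))
        }
        next
      }
      labels[f] <- cand$source
      scores[f] <- cand$score
    }
  }
  tibble::tibble(factor = factors, source = unname(labels),
                 score = unname(scores))
}

.labels_or_factors <- function(model, labels) {
  if (is.null(labels)) {
    tibble::tibble(factor = rownames(model$F), source = rownames(model$F))
  } else {
    labels |> dplyr::select(dplyr::all_of(c("factor", "source")))
  }
}

#' Per-source shares of modelled mass
#'
#' Source share = total modelled mass of the factor (over the mass species)
#' divided by the total modelled mass, as a percentage. Because profile
#' rows are normalized to sum 1 over mass species, a factor's modelled mass
#' is simply the sum of its contribution column.
#'
#' @param model A `pmf_fit`.
#' @param labels Optional labelling from [label_factors()].
#' @return A tibble: `factor`, `source`, `mass`, `share_pct` (sums to 100).
#' @export
mass_shares <- function(model, labels = NULL) {
  mass <- unname(colSums(model$G))
  tibble::tibble(factor = colnames(model$G), mass = mass) |>
    dplyr::left_join(.labels_or_factors(model, labels), by = "factor") |>
    dplyr::mutate(share_pct = 100 * .data$mass / sum(.data$mass)) |>
    dplyr::select(dplyr::all_of(c("factor", "source", "mass", "share_pct")))
}

#' Per-source factor contribution time series
#'
#' @param model A `pmf_fit` fitted to a table with timestamps.
#' @param labels Optional labelling from [label_factors()].
#' @param by_week Aggregate to ISO-week means.
#' @return A long tibble: `timestamp` (or `iso_week`), `factor`, `source`,
#'   `contribution` (ng/m3).
#' @export
contribution_series <- function(model, labels = NULL, by_week = FALSE) {
  if (is.null(model$timestamps)) abort("model was fitted without timestamps")
  out <- as_tibble(model$G) |>
    dplyr::mutate(timestamp = model$timestamps) |>
    tidyr::pivot_longer(-"timestamp", names_to = "factor",
                        values_to = "contribution") |>
    dplyr::left_join(.labels_or_factors(model, labels), by = "factor")
  if (by_week) {
    out <- out |>
      dplyr::mutate(iso_week = format(.data$timestamp, "%G-W%V")) |>
      dplyr::group_by(.data$iso_week, .data$factor, .data$source) |>
      dplyr::summarise(contribution = mean(.data$contribution),
                       .groups = "drop")
  }
  out
}

#' Per-source shares of carcinogenic and non-carcinogenic risk
#'
#' Each converted risk pseudo-species is apportioned across factors by
#' explained variation; per-source shares then aggregate the four metals
#' weighted by each metal's campaign-mean ORIGINAL (unconverted) ILCR or
#' HQ — converted values are not additive in risk space, so the weighting
#' happens on the risk scale. The aggregation rule is recorded in the
#' result's `aggregation` attribute.
#'
#' @param model A `pmf_fit` fitted to the combined species + pseudo-species
#'   matrix.
#' @param summary Campaign risk summary from [risk_summary()] (provides the
#'   per-metal weights).
#' @param labels Optional labelling from [label_factors()].
#' @return A tibble: `factor`, `source`, `ilcr_share_pct`, `hq_share_pct`
#'   (each column sums to 100).
#' @export
risk_shares <- function(model, summary, labels = NULL) {
  metals <- summary$metal
  needed <- risk_species_names(metals)
  if (!all(needed %in% model$species)) {
    abort(paste("model was fitted without the risk pseudo-species;",
                "refit on the combined table from append_risk_species()"))
  }
  ev <- explained_variation(model) |>
    tidyr::pivot_wider(names_from = "species", values_from = "share")
  evm <- as.matrix(ev[-1]); rownames(evm) <- ev$factor

  agg <- function(prefix, w) {
    shares <- evm[, paste0(prefix, metals), drop = FALSE]
    unname(drop(shares %*% (w / sum(w))))
  }
  ilcr <- agg("ILCRc_", summary$ilcr)
  hq <- agg("HQc_", summary$hq)

  out <- tibble::tibble(factor = ev$factor,
                        ilcr_share_pct = 100 * ilcr / sum(ilcr),
                        hq_share_pct = 100 * hq / sum(hq)) |>
    dplyr::left_join(.labels_or_factors(model, labels), by = "factor") |>
    dplyr::select(dplyr::all_of(c("factor", "source", "ilcr_share_pct",
                                  "hq_share_pct")))
  attr(out, "aggregation") <- "explained variation of converted pseudo-species, metals weighted by campaign-mean original ILCR/HQ"
  out
}

#' Campaign summary statistics
#'
#' Per-species mean, sd, min and max; percentage of each ion and element
#' within the summed inorganic species; and the element-only ranking by
#' descending mean.
#'
#' @param data Species table (ng/m3).
#' @param species_meta Species metadata with `species` and `group` columns.
#' @return A tibble: `species`, `group`, `mean`, `sd`, `min`, `max`,
#'   `inorganic_share_pct` (NA for carbon), `element_rank` (NA for
#'   non-elements).
#' @export
summary_statistics <- function(data, species_meta = pm25_species()) {
  long <- data |>
    tidyr::pivot_longer(-"timestamp", names_to = "species",
                        values_to = "value") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     min = min(.data$value, na.rm = TRUE),
                     max = max(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::left_join(species_meta |>
                       dplyr::select(dplyr::all_of(c("species", "group"))),
                     by = "species")
  inorg <- long$group %in% c("ion", "element")
  long$inorganic_share_pct <- ifelse(inorg,
                                     100 * long$mean / sum(long$mean[inorg]),
                                     NA_real_)
  el <- long$group %in% "element"
  long$element_rank <- NA_real_
  long$element_rank[el] <- rank(-long$mean[el])
  long |> dplyr::arrange(match(.data$species, species_meta$species))
}
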