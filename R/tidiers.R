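#' Tidy a fitted factorization
#'
#' One row per factor/species pair with the profile fraction and the
#' explained-variation share — the long form behind the classic profile
#' bar-plus-dots display.
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return A tibble: `factor`, `species`, `profile`, `explained_variation`.
#' @export
tidy.pmf_fit <- function(x, ...) {
  prof <- as_tibble(x$F, rownames = "factor") |>
    tidyr::pivot_longer(-"factor", names_to = "species",
                        values_to = "profile")
  ev <- explained_variation(x) |>
    dplyr::rename(explained_variation = "share")
  prof |>
    dplyr::left_join(ev, by = c("factor", "species")) |>
    dplyr::mutate(species = factor(.data$species, levels = x$species))
}

#' One-row summary of a fitted factorization
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return A tibble: `k`, `Q`, `Qexp`, `q_ratio`, `n_iter`, `converged`,
#'   `seed`, `start_index`.
#' @export
glance.pmf_fit <- function(x, ...) {
  tibble::tibble(k = nrow(x$F), Q = x$Q, Qexp = x$Qexp,
                 q_ratio = x$Q / x$Qexp, n_iter = x$n_iter,
                 converged = x$converged, seed = x$seed,
                 start_index = x$start_index)
}

#' Tidy a factor-number scan
#'
#' @param x A `pmf_scan`.
#' @param ... Unused.
#' @return The per-K summary tibble (`k`, `Q`, `Qexp`, `q_ratio`,
#'   `n_converged`).
#' @export
tidy.pmf_scan <- function(x, ...) x$summary

#' One-row summary of a factor-number scan
#'
#' @param x A `pmf_scan`.
#' @param ... Unused.
#' @return A tibble: `suggested_k`, `k_min`, `k_max`, `n_starts`, `seed`.
#' @export
glance.pmf_scan <- function(x, ...) {
  tibble::tibble(suggested_k = x$suggested_k,
                 k_min = min(x$summary$k), k_max = max(x$summary$k),
                 n_starts = x$n_starts, seed = x$seed)
}
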