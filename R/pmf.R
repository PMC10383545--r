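#' Expected value of the weighted objective Q
#'
#' The degrees-of-freedom convention: `Qexp = n*m - K*(n+m)`. A
#' well-specified model (uncertainties matching the true error scale) has
#' Q/Qexp near 1.
#'
#' @param n Number of samples.
#' @param m Number of species.
#' @param k Number of factors (0 allowed: no parameters).
#' @return Qexp, a positive count.
#' @export
q_expected <- function(n, m, k) {
  q <- n * m - k * (n + m)
  if (q <= 0) {
    abort(sprintf("over-parameterized: n*m = %d <= K*(n+m) = %d",
                  n * m, k * (n + m)))
  }
  q
}

.as_fit_input <- function(data, uncertainty) {
  if (is.data.frame(data)) {
    x <- species_matrix(data)
    ts <- data$timestamp
  } else {
    x <- as.matrix(data)
    ts <- NULL
  }
  u <- as.matrix(uncertainty)
  if (!all(dim(u) == dim(x))) abort("uncertainty must match the data shape")
  if (!all(is.finite(x)) || !all(is.finite(u))) {
    abort("non-finite values in data or uncertainty; apply a missing policy first")
  }
  if (any(u <= 0)) abort("uncertainties must be strictly positive")
  list(x = x, u = u, timestamps = ts)
}

# one solve from a seeded random start
.fit_one <- function(x, u, k, seed, start_index, max_iter, tol, n_stable,
                     method = c("als", "mu")) {
  method <- match.arg(method)
  n <- nrow(x); m <- ncol(x)
  scale0 <- sqrt(mean(x) / k)
  init <- with_seed((abs(sub_seed(seed, "init")) + 7919L * start_index) %% .Machine$integer.max,
                    list(G = matrix(abs(rnorm(n * k)) * scale0, n, k),
                         F = matrix(abs(rnorm(k * m)) * scale0, k, m)))
  core <- if (method == "als") wanls_core else wnmf_core
  core(x, 1 / u^2, init$G, init$F, max_iter, tol, n_stable)
}

#' Fit an uncertainty-weighted non-negative factorization
#'
#' Minimizes `Q = sum_ij ((x_ij - (GF)_ij) / u_ij)^2` over non-negative
#' contributions G (n x K) and profiles F (K x m). The default solver is
#' alternating exact weighted non-negative least squares (`method = "als"`):
#' each sweep solves every row of G and column of F to optimality by an
#' active-set NNLS, so Q is non-increasing and solutions carry exact zeros —
#' the right geometry for tracer-sparse source profiles. Weighted
#' multiplicative (Lee-Seung) updates are available as `method = "mu"`; they
#' are also monotone but approach the boundary only asymptotically. Several
#' random starts may be run; the lowest-Q solution is kept. After fitting, each profile row is
#' normalized to sum to 1 over the mass species (risk pseudo-species are
#' excluded from the normalizer) with the scale absorbed into G, so G
#' columns are mass contributions in ng/m3.
#'
#' @param data Species table (timestamp + species columns, possibly
#'   including risk pseudo-species) or a bare numeric matrix.
#' @param uncertainty Matrix of per-cell uncertainties, as from
#'   [uncertainty_matrix()].
#' @param k Number of factors.
#' @param seed Integer seed; start `s` uses a documented sub-seed of it.
#' @param n_starts Number of random starts (best kept).
#' @param max_iter Maximum update iterations per start.
#' @param tol Relative change in Q treated as stationary.
#' @param n_stable Consecutive stationary iterations required to declare
#'   convergence.
#' @param method Solver: `"als"` (alternating exact weighted NNLS, default)
#'   or `"mu"` (weighted multiplicative updates).
#' @param mass_species Species over which profile rows are normalized;
#'   defaults to all non-pseudo-species columns present.
#' @return A `pmf_fit` object: matrices `G`, `F`, scalars `Q`, `Qexp`,
#'   `n_iter`, `converged`, `seed`, `start_index`, the per-iteration
#'   `q_trace` of the winning start, and bookkeeping (`species`,
#'   `mass_species`, `timestamps`, `n_starts`).
#' @export
pmf_fit <- function(data, uncertainty, k, seed = 1, n_starts = 1,
                    max_iter = 2000, tol = 1e-6, n_stable = 10,
                    mass_species = NULL, method = c("als", "mu")) {
  method <- match.arg(method)
  inp <- .as_fit_input(data, uncertainty)
  x <- inp$x; u <- inp$u
  n <- nrow(x); m <- ncol(x)
  if (k > min(n, m)) abort("k must be <= min(n_samples, n_species)")

  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- .fit_one(x, u, k, seed, s, max_iter, tol, n_stable, method)
    if (is.null(best) || res$Q < best$Q) {
      best <- res
      best$start_index <- s
    }
  }
  if (!best$converged) {
    warn(sprintf("best start (%d) did not converge in %d iterations",
                 best$start_index, max_iter))
  }

  species <- colnames(x)
  if (is.null(species)) species <- paste0("V", seq_len(m))
  if (is.null(mass_species)) {
    mass_species <- species[!grepl("^(ILCRc|HQc)_", species)]
  }
  G <- best$G
  F <- best$F
  colnames(F) <- species
  mi <- match(mass_species, species)
  rs <- rowSums(F[, mi, drop = FALSE])
  rs[rs == 0] <- 1
  F <- F / rs
  G <- sweep(G, 2, rs, `*`)
  rownames(F) <- colnames(G) <- paste0("factor_", seq_len(k))

  structure(list(G = G, F = F, Q = best$Q,
                 Qexp = q_expected(n, m, k),
                 q_trace = as.numeric(best$q_trace),
                 n_iter = best$n_iter, converged = best$converged,
                 seed = seed, start_index = best$start_index,
                 n_starts = n_starts, species = species,
                 mass_species = mass_species,
                 timestamps = inp$timestamps),
            class = "pmf_fit")
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat(sprintf("<pmf_fit> %d factors, %d x %d matrix\n",
              nrow(x$F), nrow(x$G), ncol(x$F)))
  cat(sprintf("  Q = %.4g, Qexp = %d, Q/Qexp = %.3f\n", x$Q, x$Qexp,
              x$Q / x$Qexp))
  cat(sprintf("  %s after %d iterations (start %d of %d, seed %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$start_index, x$n_starts, x$seed))
  invisible(x)
}

#' Scan factor numbers and tabulate Q/Qexp
#'
#' Fits every K in `k_min:k_max` from `n_starts` random starts each,
#' retaining the best-Q model per K. The suggested factor number is the
#' smallest K whose relative drop in Q/Qexp to K+1 falls below
#' `elbow_threshold` — i.e. the point where adding a factor stops paying.
#'
#' @inheritParams pmf_fit
#' @param k_min,k_max Factor-number range.
#' @param elbow_threshold Relative Q/Qexp drop below which the curve is
#'   considered flat (default 10%).
#' @param keep_models Keep every best-per-K `pmf_fit` in the result.
#' @return A `pmf_scan` object: tibble `summary` (`k`, `Q`, `Qexp`,
#'   `q_ratio`, `n_converged`), `suggested_k`, and optionally `models`.
#' @export
scan_factors <- function(data, uncertainty, k_min = 1, k_max = 10,
                         n_starts = 10, seed = 1, max_iter = 2000,
                         tol = 1e-6, elbow_threshold = 0.1,
                         keep_models = TRUE, mass_species = NULL,
                         method = c("als", "mu")) {
  method <- match.arg(method)
  stopifnot(k_min >= 1, k_max >= k_min)
  models <- list()
  rows <- purrr::map(k_min:k_max, function(k) {
    fits <- purrr::map(seq_len(n_starts), function(s) {
      suppressWarnings(
        pmf_fit(data, uncertainty, k, seed = seed + 31L * s, n_starts = 1,
                max_iter = max_iter, tol = tol, mass_species = mass_species,
                method = method))
    })
    conv <- purrr::map_lgl(fits, "converged")
    qs <- purrr::map_dbl(fits, "Q")
    pick <- if (any(conv)) which(conv)[which.min(qs[conv])] else which.min(qs)
    best <- fits[[pick]]
    models[[as.character(k)]] <<- best
    tibble::tibble(k = k, Q = best$Q, Qexp = best$Qexp,
                   q_ratio = best$Q / best$Qexp, n_converged = sum(conv))
  }) |> dplyr::bind_rows()

  suggested <- NA_integer_
  if (nrow(rows) > 1) {
    drop_frac <- -diff(rows$q_ratio) / head(rows$q_ratio, -1)
    flat <- which(drop_frac < elbow_threshold)
    if (length(flat)) suggested <- rows$k[flat[1]]
  }

  structure(list(summary = rows, suggested_k = suggested,
                 models = if (keep_models) models else NULL,
                 n_starts = n_starts, seed = seed,
                 elbow_threshold = elbow_threshold),
            class = "pmf_scan")
}

#' @export
print.pmf_scan <- function(x, ...) {
  cat("<pmf_scan>\n")
  print(x$summary)
  cat(sprintf("suggested number of factors: %s\n", x$suggested_k))
  invisible(x)
}

#' Reconstruction diagnostics: slope and R-squared
#'
#' Ordinary least-squares fit of reconstructed values against input values
#' over all modelled cells; slope near 1 and high R-squared indicate the
#' model tracks the input variation.
#'
#' @param data Species table or matrix the model was fitted to.
#' @param model A `pmf_fit`.
#' @return A tibble with `slope`, `intercept`, `r_squared`, `n_cells`.
#' @export
model_fit_stats <- function(data, model) {
  x <- if (is.data.frame(data)) species_matrix(data) else as.matrix(data)
  recon <- model$G %*% model$F
  xv <- as.numeric(x); rv <- as.numeric(recon)
  if (stats::var(xv) == 0) abort("input has no variance; slope undefined")
  slope <- stats::cov(xv, rv) / stats::var(xv)
  r2 <- if (stats::var(rv) > 0) stats::cor(xv, rv)^2 else 0
  tibble::tibble(slope = slope,
                 intercept = mean(rv) - slope * mean(xv),
                 r_squared = r2,
                 n_cells = length(xv))
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

#' Match estimated factors to reference profiles
#'
#' Finds the one-to-one assignment of estimated to reference factors that
#' maximizes the summed cosine similarity between profile rows (exhaustive
#' over permutations for K <= 8, greedy beyond). Ties break by first-index
#' order.
#'
#' With `scale = "species"` (the default) each matrix's species columns are
#' scaled to unit norm across factors before comparison, the same
#' species-relative view used when profiles are displayed as
#' percent-of-species. This weights every species equally, so similarity
#' reflects the factor's chemical signature; raw mass-fraction rows
#' (`scale = "none"`) are instead dominated by the bulk species (OC, EC,
#' nitrate, sulfate), whose allocation carries most rotational uncertainty.
#'
#' @param f_est,f_ref K x m profile matrices with matching columns.
#' @param scale `"species"` (species-relative, default) or `"none"` (raw
#'   rows).
#' @return A tibble: `factor` (estimated index), `reference` (matched
#'   reference index), `reference_name` (if `f_ref` has row names),
#'   `cosine`.
#' @export
match_factors <- function(f_est, f_ref, scale = c("species", "none")) {
  stopifnot(nrow(f_est) == nrow(f_ref), ncol(f_est) == ncol(f_ref))
  scale <- match.arg(scale)
  if (scale == "species") {
    f_est <- sweep(f_est, 2, pmax(sqrt(colSums(f_est^2)), 1e-300), `/`)
    f_ref <- sweep(f_ref, 2, pmax(sqrt(colSums(f_ref^2)), 1e-300), `/`)
  }
  k <- nrow(f_est)
  sim <- outer(seq_len(k), seq_len(k),
               Vectorize(function(i, j) .cosine(f_est[i, ], f_ref[j, ])))
  if (k <= 8) {
    perms <- .permutations(k)
    scores <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(k), p)]))
    best <- unname(perms[which.max(scores), ])
  } else {
    best <- integer(k)
    taken <- logical(k)
    for (i in order(-apply(sim, 1, max))) {
      j <- order(-sim[i, ])
      j <- j[!taken[j]][1]
      best[i] <- j
      taken[j] <- TRUE
    }
  }
  tibble::tibble(
    factor = seq_len(k),
    reference = best,
    reference_name = if (!is.null(rownames(f_ref))) rownames(f_ref)[best]
      else as.character(best),
    cosine = sim[cbind(seq_len(k), best)]
  )
}
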