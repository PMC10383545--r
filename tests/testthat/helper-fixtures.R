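# Small fixtures shared across tests; everything is generated in code.

# a tiny 3-source campaign over 8 species, cheap enough for repeated fits
tiny_sources <- function() {
  list(
    source_spec("alpha", c(A = 900, B = 80, C = 20), 1.0,
                ar1_coefficient = 0.5, lognormal_sigma = 0.6),
    source_spec("beta", c(B = 500, D = 300, E = 40), 0.84,
                ar1_coefficient = 0.5, lognormal_sigma = 0.6),
    source_spec("gamma", c(F = 600, G = 150, H = 30, A = 60), 0.84,
                ar1_coefficient = 0.5, lognormal_sigma = 0.6)
  )
}

tiny_species <- function() LETTERS[1:8]

tiny_unc_spec <- function(cv = 0.1, dl = 2) {
  tibble::tibble(species = tiny_species(), dl = dl, cv = cv)
}

tiny_campaign <- function(n = 250, seed = 11, cv = 0.1) {
  simulate_campaign(n_samples = n, sources = tiny_sources(),
                    species = tiny_species(),
                    unc_spec = tiny_unc_spec(cv = cv), seed = seed)
}

# species table wrapper around a bare matrix
as_species_table <- function(x, species = colnames(x)) {
  colnames(x) <- species
  dplyr::bind_cols(
    tibble::tibble(timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                     3600 * (seq_len(nrow(x)) - 1)),
    tibble::as_tibble(x))
}

# hand-assembled pmf_fit-shaped object for apportionment unit tests
fake_fit <- function(G, F, mass_species = colnames(F), timestamps = NULL) {
  rownames(F) <- colnames(G) <- paste0("factor_", seq_len(ncol(G)))
  structure(list(G = G, F = F, Q = 0, Qexp = 1, q_trace = 0, n_iter = 0,
                 converged = TRUE, seed = 0, start_index = 1, n_starts = 1,
                 species = colnames(F), mass_species = mass_species,
                 timestamps = timestamps),
            class = "pmf_fit")
}
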