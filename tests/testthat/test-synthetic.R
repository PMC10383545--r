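test_that("profile generation normalizes tracer weights", {
  s1 <- source_spec("one", c(A = 1), 1)
  expect_equal(unname(generate_profiles(list(s1), c("A", "B"))[1, ]),
               c(1, 0))
  s2 <- source_spec("two", c(A = 3, B = 1), 1)
  expect_equal(unname(generate_profiles(list(s2), c("A", "B"))[1, ]),
               c(0.75, 0.25))
  expect_error(generate_profiles(list(source_spec("bad", c(Q9 = 1), 1)),
                                 c("A", "B")), "Q9")
})

test_that("default 7-source profiles put each primary tracer on its source", {
  primary <- c(secondary = "NO3", biomass_burning = "K", traffic = "Mn",
               fugitive_dust = "Ca", industry = "Cd", coal_combustion = "As",
               heavy_oil = "V")
  sources <- default_sources()
  f <- generate_profiles(sources)
  expect_equal(dim(f), c(7, 18))
  expect_equal(rowSums(f), setNames(rep(1, 7), rownames(f)))
  expect_true(all(f >= 0))
  # emission-weighted (mass x profile) column argmax identifies the source
  mass <- vapply(sources, function(s) s$mean_contribution, 0)
  em <- mass * f
  for (src in names(primary)) {
    expect_identical(rownames(f)[which.max(em[, primary[src]])], src)
  }
})

test_that("contribution series honour their moments and determinism", {
  s <- source_spec("flat", c(A = 1), 2.5, ar1_coefficient = 0,
                   lognormal_sigma = 0)
  g <- generate_contributions(10, list(s), seed = 4)
  expect_equal(unname(g[, 1]), rep(2500, 10))    # ug -> ng, degenerate noise

  s2 <- source_spec("noisy", c(A = 1), 2.5, ar1_coefficient = 0,
                    lognormal_sigma = 0.5)
  g2 <- generate_contributions(5000, list(s2), seed = 4)
  expect_lt(abs(mean(g2[, 1]) / 2500 - 1), 0.05)
  expect_true(all(g2 >= 0))

  expect_identical(generate_contributions(100, list(s2), seed = 9),
                   generate_contributions(100, list(s2), seed = 9))
  expect_false(identical(generate_contributions(100, list(s2), seed = 9),
                         generate_contributions(100, list(s2), seed = 10)))

  expect_error(source_spec("x", c(A = 1), 1, ar1_coefficient = 1),
               "ar1_coefficient")
  expect_error(source_spec("x", c(A = 1), 1, ar1_coefficient = -0.1),
               "ar1_coefficient")
})

test_that("zero-noise synthesis reproduces G %*% F to machine precision", {
  src <- tiny_sources()
  f <- generate_profiles(src, tiny_species())
  g <- generate_contributions(50, src, seed = 2)
  spec0 <- tibble::tibble(species = tiny_species(), dl = 0, cv = 0)
  out <- synthesize_campaign(g, f, spec0, seed = 2)
  expect_equal(unname(species_matrix(out$data)), unname(g %*% f),
               tolerance = 1e-14)
  expect_equal(out$n_truncated, 0)
})

test_that("synthetic campaign matches the study dimensions", {
  sim <- simulate_campaign(seed = 21)
  expect_equal(dim(sim$data), c(2622, 19))   # timestamp + 18 species
  expect_equal(dim(sim$truth$G_true), c(2622, 7))
  expect_equal(dim(sim$truth$F_true), c(7, 18))
  expect_true(all(species_matrix(sim$data) >= 0))
  expect_lt(sim$truncation_fraction, 0.01)
})

test_that("relative noise at CV = 0.1 has the requested spread", {
  src <- tiny_sources()
  f <- generate_profiles(src, tiny_species())
  g <- generate_contributions(1500, src, seed = 6)
  spec <- tibble::tibble(species = tiny_species(), dl = 0, cv = 0.1)
  out <- synthesize_campaign(g, f, spec, seed = 6)
  truth <- g %*% f
  keep <- truth > 1          # avoid zero cells of sparse profiles
  rel <- (species_matrix(out$data)[keep] - truth[keep]) / truth[keep]
  expect_gt(length(rel), 1e4)
  expect_lt(abs(sd(rel) - 0.1), 0.005)
})

test_that("seeded campaigns are bit-reproducible", {
  a <- simulate_campaign(n_samples = 40, sources = tiny_sources(),
                         species = tiny_species(),
                         unc_spec = tiny_unc_spec(), seed = 123)
  b <- simulate_campaign(n_samples = 40, sources = tiny_sources(),
                         species = tiny_species(),
                         unc_spec = tiny_unc_spec(), seed = 123)
  expect_identical(species_matrix(a$data), species_matrix(b$data))
  expect_identical(a$truth$G_true, b$truth$G_true)
})

test_that("field blanks hit the requested spread, non-negative, seeded", {
  b0 <- generate_field_blanks(c("a", "b"), blank_sd = 0, n_blanks = 5)
  expect_true(all(b0$a == b0$a[1]))

  b <- generate_field_blanks("a", blank_sd = 0.5, n_blanks = 1e4, seed = 8)
  expect_lt(abs(sd(b$a) / 0.5 - 1), 0.05)
  expect_true(all(b$a >= 0))

  expect_identical(generate_field_blanks("a", 0.5, 20, seed = 3),
                   generate_field_blanks("a", 0.5, 20, seed = 3))
  expect_error(generate_field_blanks("a", 0.5, n_blanks = 1), "sd undefined")
})

test_that("optional missingness knocks out the requested fraction", {
  sim <- simulate_campaign(n_samples = 200, sources = tiny_sources(),
                           species = tiny_species(),
                           unc_spec = tiny_unc_spec(), seed = 5,
                           missing_fraction = 0.05)
  frac <- mean(is.na(species_matrix(sim$data)))
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})
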