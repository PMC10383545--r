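test_that("explained variation is a per-species partition of unity", {
  set.seed(5)
  G <- matrix(abs(rnorm(40 * 3, 10, 3)), 40, 3)
  F <- matrix(abs(rnorm(3 * 6)), 3, 6,
              dimnames = list(NULL, letters[1:6]))
  F[2, 4] <- 0
  fit <- fake_fit(G, F)
  ev <- explained_variation(fit)
  sums <- ev |> dplyr::group_by(species) |> dplyr::summarise(s = sum(share))
  expect_equal(sums$s, rep(1, 6), tolerance = 1e-12)
  expect_equal(ev$share[ev$factor == "factor_2" & ev$species == "d"], 0)

  one <- fake_fit(G[, 1, drop = FALSE], F[1, , drop = FALSE])
  ev1 <- explained_variation(one)
  expect_equal(ev1$share, rep(1, 6))
})

test_that("tracer labelling is rule-driven and permutation invariant", {
  G <- matrix(10, 20, 2)
  F <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.6, 0.3))
  colnames(F) <- c("NO3", "K", "Ba")
  fit <- fake_fit(G, F)

  expect_identical(label_factors(fit, list())$source, c("unassigned",
                                                        "unassigned"))
  rules <- list(tracer_rule("secondary", "NO3"),
                tracer_rule("biomass_burning", "K"))
  labs <- label_factors(fit, rules)
  expect_identical(labs$source, c("secondary", "biomass_burning"))

  # permuting factor order permutes rows but not the factor -> source map
  fit2 <- fake_fit(G[, 2:1], F[2:1, ])
  labs2 <- label_factors(fit2, rules)
  expect_identical(labs2$source, c("biomass_burning", "secondary"))

  # single factor, single matching rule
  labs3 <- label_factors(fake_fit(G[, 1, drop = FALSE],
                                  F[1, , drop = FALSE]),
                         list(tracer_rule("secondary", "NO3")))
  expect_identical(labs3$source, "secondary")
})

test_that("conflicting rule claims warn and resolve by summed share", {
  G <- matrix(10, 20, 2)
  F <- rbind(c(0.5, 0.45, 0.05), c(0.01, 0.01, 0.98))
  colnames(F) <- c("Cd", "As", "OC")
  fit <- fake_fit(G, F)
  rules <- list(tracer_rule("industry", "Cd"),
                tracer_rule("coal_combustion", "As"))
  expect_warning(labs <- label_factors(fit, rules), "claimed by both")
  expect_identical(labs$source[1], "industry")   # higher Cd share wins
  expect_identical(labs$source[2], "unassigned")
})

test_that("mass shares are percentages of modelled mass", {
  G <- cbind(rep(30, 10), rep(10, 10))
  F <- rbind(c(0.5, 0.5), c(0.5, 0.5)); colnames(F) <- c("a", "b")
  ms <- mass_shares(fake_fit(G, F))
  expect_equal(sum(ms$share_pct), 100, tolerance = 1e-12)
  expect_equal(ms$share_pct, c(75, 25))

  one <- mass_shares(fake_fit(G[, 1, drop = FALSE], F[1, , drop = FALSE]))
  expect_equal(one$share_pct, 100)
})

test_that("risk shares aggregate pseudo-species by original-risk weights", {
  sp <- c("Cr", "Ni", "As", "Cd", risk_species_names())
  K <- 2
  F <- matrix(0.5, K, length(sp), dimnames = list(NULL, sp))
  # factor 1 carries ALL the risk pseudo-species signal
  F[1, risk_species_names()] <- 1
  F[2, risk_species_names()] <- 0
  G <- matrix(5, 30, K)
  fit <- fake_fit(G, F, mass_species = c("Cr", "Ni", "As", "Cd"))

  sim <- simulate_campaign(n_samples = 30, seed = 2)
  rsum <- risk_summary(sim$data)
  shares <- risk_shares(fit, rsum)
  expect_equal(shares$ilcr_share_pct, c(100, 0))
  expect_equal(shares$hq_share_pct, c(100, 0))

  # equal loadings -> equal shares
  F2 <- matrix(0.5, K, length(sp), dimnames = list(NULL, sp))
  eq <- risk_shares(fake_fit(G, F2, mass_species = c("Cr", "Ni", "As", "Cd")),
                    rsum)
  expect_equal(eq$ilcr_share_pct, c(50, 50), tolerance = 1e-9)
  expect_equal(sum(eq$hq_share_pct), 100, tolerance = 1e-9)

  # refusing to run without the pseudo-species columns
  bare <- fake_fit(G, F2[, 1:4], mass_species = c("Cr", "Ni", "As", "Cd"))
  expect_error(risk_shares(bare, rsum), "pseudo-species")
})

test_that("summary statistics cover moments, shares and element ranking", {
  x <- cbind(OC = rep(7, 6), NO3 = rep(4, 6), SO4 = rep(4, 6),
             Fe = rep(3, 6), Si = rep(2, 6), Ca = rep(1, 6))
  dat <- as_species_table(x)
  st <- summary_statistics(dat)
  oc <- st[st$species == "OC", ]
  expect_equal(oc$sd, 0)
  expect_equal(oc$min, oc$mean)
  expect_equal(oc$max, oc$mean)
  expect_true(is.na(oc$inorganic_share_pct))
  # equal means share the inorganic sum equally
  expect_equal(st$inorganic_share_pct[st$species == "NO3"],
               st$inorganic_share_pct[st$species == "SO4"])
  # element ranking by descending mean: Fe > Si > Ca
  expect_equal(st$element_rank[st$species == "Fe"], 1)
  expect_equal(st$element_rank[st$species == "Si"], 2)
  expect_equal(st$element_rank[st$species == "Ca"], 3)
  expect_equal(sum(st$inorganic_share_pct, na.rm = TRUE), 100,
               tolerance = 1e-9)
})

test_that("contribution series supports ISO-week aggregation", {
  sim <- tiny_campaign(n = 24 * 15)     # just over two ISO weeks
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  fit <- pmf_fit(sim$data, u, k = 3, seed = 1, n_starts = 2)
  cs <- contribution_series(fit)
  expect_equal(nrow(cs), 24 * 15 * 3)
  wk <- contribution_series(fit, by_week = TRUE)
  expect_true(all(grepl("^\\d{4}-W\\d{2}$", wk$iso_week)))
  expect_lt(nrow(wk), nrow(cs))
})
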