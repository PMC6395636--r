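# Infection gates, lysis-lysogeny decision, induction, decay, mortality.

test_that("lysogeny curves are zero at zero, half at K, monotone and bounded", {
  cv <- lysogeny_curve(p_max = 0.8, half_density = 20, hill_exponent = 2)
  expect_equal(lysogeny_probability(0, cv), 0)
  expect_equal(lysogeny_probability(20, cv), 0.4)

  set.seed(1)
  for (i in 1:20) {
    cv <- lysogeny_curve(p_max = runif(1), half_density = runif(1, 0.5, 200),
                         hill_exponent = runif(1, 1, 4))
    p <- lysogeny_probability(0:500, cv)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0 & p <= cv$p_max))
  }

  # stock curves: the high-density preset is pointwise weakest
  l1 <- lysogeny_preset("Lysogeny1")
  l2 <- lysogeny_preset("Lysogeny2")
  l3 <- lysogeny_preset("Lysogeny3")
  expect_true(l1$half_density <= l2$half_density)
  expect_true(l2$half_density < l3$half_density)
  n <- c(1:100, seq(200, 10000, by = 200))
  expect_true(all(lysogeny_probability(n, l3) <= lysogeny_probability(n, l1)))
  expect_true(all(lysogeny_probability(n, l3) <= lysogeny_probability(n, l2)))
})

test_that("infection gates resolve encounters in the specified order", {
  reg <- tiny_registry()
  host_res <- bacterium(reg$bacteria$S1, resisted_phage_phenotypes = "a")
  v <- phage_particle(reg$phages$P)
  out <- attempt_infection(v, host_res, reg, local_phage_count = 1)
  expect_identical(out$kind, "resistant_host")
  expect_false(out$virion_consumed)

  # all gates open for a virulent phage: lysis, always
  host <- bacterium(reg$bacteria$S1)
  set.seed(1)
  kinds <- replicate(50, attempt_infection(v, host, reg, 1)$kind)
  expect_true(all(kinds == "lysis_initiated"))

  # superinfection exclusion with abort probability 1
  lysogen <- bacterium(reg$bacteria$S1,
                       prophages = list(list(species = "P",
                                             attachment_phenotype = "a")))
  kinds <- replicate(50, attempt_infection(v, lysogen, reg, 1)$kind)
  expect_true(all(kinds == "aborted_superinfection"))

  expect_error(
    attempt_infection(phage_particle("P", attachment_phenotype = "zz"),
                      host, reg, 1),
    "unknown")
})

test_that("temperate infections lysogenize at the curve probability", {
  reg <- tiny_registry(lifestyle = "temperate",
                       curve = lysogeny_curve(p_max = 1, half_density = 5,
                                              hill_exponent = 2))
  host <- bacterium(reg$bacteria$S1)
  v <- phage_particle(reg$phages$P)
  set.seed(2)
  # far above the half-density the decision saturates at p_max = 1
  kinds <- replicate(1e4, attempt_infection(v, host, reg,
                                            local_phage_count = 500)$kind)
  expect_true(mean(kinds == "lysogenized") > 0.995)

  # a lysogenized host carries the new prophage
  out <- attempt_infection(v, host, reg, 500)
  expect_identical(out$kind, "lysogenized")
  expect_identical(out$host$prophages[[1]]$species, "P")

  # with full superinfection exclusion, re-lysogenization never happens
  kinds2 <- replicate(200, attempt_infection(v, out$host, reg, 500)$kind)
  expect_true(all(kinds2 == "aborted_superinfection"))
})

test_that("lysis releases the configured burst with mutated phenotypes", {
  cfg <- tiny_config(phage_diffusion_radius = 1L,
                     phage_cap_per_location = 10000L)
  # burst 0: host dies, nothing released
  st <- tiny_state(cfg, tiny_registry(burst = 0L))
  st <- place_bacteria(st, "S1", 1, locations = 55L)
  st$lys_species[55] <- 1L; st$lys_pheno[55] <- 1L
  st2 <- resolve_lysis(st, 55L)
  expect_equal(st2$b_species[55], 0L)
  expect_equal(length(st2$p_loc), 0)
  expect_equal(unname(st2$tally["lyses"]), 1)

  # burst 50, no mutation: 50 parental-phenotype virions near the host
  st <- tiny_state(cfg, tiny_registry(burst = 50L, mu_att = 0))
  st <- place_bacteria(st, "S1", 1, locations = 55L)
  st$lys_species[55] <- 1L; st$lys_pheno[55] <- 1L
  set.seed(3)
  st2 <- resolve_lysis(st, 55L)
  expect_equal(length(st2$p_loc), 50)
  expect_true(all(st2$p_pheno == 1L))
  nb <- c(55L, phagelattice:::loc_index(
    neighborhood(c(4, 5), 1, cfg)[, 1], neighborhood(c(4, 5), 1, cfg)[, 2],
    cfg))
  expect_true(all(st2$p_loc %in% nb))

  # pooled mutant fraction across many lyses matches mu_attachment
  st <- tiny_state(tiny_config(phage_diffusion_radius = 0L,
                               phage_cap_per_location = 100000L),
                   tiny_registry(burst = 100L, mu_att = 1e-2))
  set.seed(4)
  st <- place_bacteria(st, "S1", 100)
  occ <- which(st$b_species > 0)
  st$lys_species[occ] <- 1L; st$lys_pheno[occ] <- 1L
  total <- 0L; mutants <- 0L
  for (i in 1:10) {
    st_i <- st
    st_i <- resolve_lyses(st_i)
    total <- total + length(st_i$p_pheno)
    mutants <- mutants + sum(st_i$p_pheno != 1L)
  }
  expect_equal(total, 1e5)
  expect_lt(abs(mutants - total * 1e-2),
            3 * sqrt(total * 1e-2 * (1 - 1e-2)))
})

test_that("prophages induce at the configured rate, amplified under stress", {
  reg <- tiny_registry(lifestyle = "temperate",
                       curve = lysogeny_curve(), induction = 0.01,
                       stress = 10)
  cfg <- lattice_config(width = 400L, height = 250L)  # 1e5 lysogens
  st <- simulation_state(cfg, reg,
                         kill = kill_model(mic_threshold = 1))
  st$b_species[] <- 1L
  st$b_proph[] <- 1L   # prophage combo (P, phenotype a)

  # no prophages: nothing induces
  bare <- st; bare$b_proph[] <- 0L
  set.seed(5)
  expect_equal(unname(induce_prophages(bare)$tally["inductions"]), 0)

  set.seed(5)
  st2 <- induce_prophages(st)
  k <- unname(st2$tally["inductions"])
  expect_lt(abs(k - 1e5 * 0.01), 3 * sqrt(1e5 * 0.01 * 0.99))
  expect_equal(sum(st2$lys_species > 0), k)

  # antibiotic stress multiplies the hazard tenfold
  st$field$conc[] <- 5
  set.seed(6)
  k_stress <- unname(induce_prophages(st)$tally["inductions"])
  expect_lt(abs(k_stress - 1e5 * 0.1), 3 * sqrt(1e5 * 0.1 * 0.9))
})

test_that("free virions decay with a constant per-iteration hazard", {
  st <- tiny_state(tiny_config(phage_cap_per_location = 100000L),
                   tiny_registry(decay = 0))
  set.seed(7)
  st <- place_phages(st, "P", 1000)
  st2 <- decay_free_phages(st)
  expect_equal(length(st2$p_loc), 1000)
  expect_true(all(st2$p_age == 1L))     # ages increment even without decay

  st$registry$ps_decay[] <- 1
  expect_equal(length(decay_free_phages(st)$p_loc), 0)

  st$registry$ps_decay[] <- 0.1
  big <- st
  n <- 1e4
  big$p_loc <- rep(1L, n); big$p_species <- rep(1L, n)
  big$p_pheno <- rep(1L, n); big$p_age <- integer(n)
  set.seed(8)
  removed <- n - length(decay_free_phages(big)$p_loc)
  expect_lt(abs(removed - n * 0.1), 3 * sqrt(n * 0.1 * 0.9))
})

test_that("mortality combines basal and threshold antibiotic killing", {
  reg <- tiny_registry()
  cfg <- lattice_config(width = 100L, height = 100L)

  # basal 0, no antibiotic: nobody dies
  st <- simulation_state(cfg, reg,
                         kill = kill_model(basal_death_prob = 0,
                                           antibiotic_kill_prob = 0.95))
  st$b_species[] <- 1L
  set.seed(9)
  expect_equal(sum(apply_mortality(st)$b_species > 0), 10000)

  # certain kill wipes a sensitive population in one pass
  st$kill$antibiotic_kill_prob <- 1
  st$field$conc[] <- 5
  expect_equal(sum(apply_mortality(st)$b_species > 0), 0)

  # resistant cells ignore the antibiotic term
  st$b_abres[] <- TRUE
  expect_equal(sum(apply_mortality(st)$b_species > 0), 10000)

  # basal 0.02 on 1e4 cells: binomial death count
  st2 <- simulation_state(cfg, reg,
                          kill = kill_model(basal_death_prob = 0.02,
                                            antibiotic_kill_prob = 0))
  st2$b_species[] <- 2L
  set.seed(10)
  dead <- 10000 - sum(apply_mortality(st2)$b_species > 0)
  expect_lt(abs(dead - 200), 3 * sqrt(10000 * 0.02 * 0.98))
})
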