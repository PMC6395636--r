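# Species, fitness, roulette selection, mutation and genotype labels.

test_that("fitness composes multiplicative resistance costs", {
  sp <- bacterial_species("X", base_growth_rate = 1,
                          cost_antibiotic_resistance = 0.1,
                          cost_phage_resistance = 0.05)
  expect_equal(fitness(bacterium(sp)), 1)
  expect_equal(fitness(bacterium(sp, antibiotic_resistant = TRUE)), 0.9)
  expect_equal(fitness(bacterium(sp, antibiotic_resistant = TRUE,
                                 resisted_phage_phenotypes = "a")),
               1 * 0.9 * 0.95)  # = 0.855, the full product

  # invariant under acquisition order of resistances
  c1 <- bacterium(sp, resisted_phage_phenotypes = c("a", "b"))
  c2 <- bacterium(sp, resisted_phage_phenotypes = c("b", "a"))
  expect_equal(fitness(c1), fitness(c2))

  expect_error(bacterial_species("X", cost_phage_resistance = 1), "\\[0,1\\)")
  expect_error(bacterial_species("bad name"), "invalid")
})

test_that("roulette selection matches the normalized fitness distribution", {
  sp <- bacterial_species("X")
  solo <- bacterium(sp)
  expect_identical(roulette_select(list(solo)), solo)
  expect_error(roulette_select(list()), "nonempty")

  # a zero-fitness candidate is never drawn against a positive one
  dead_sp <- bacterial_species("D", base_growth_rate = 0)
  set.seed(1)
  picks <- replicate(200, roulette_select(
    list(bacterium(dead_sp), bacterium(sp)))$species$name)
  expect_true(all(picks == "X"))

  # two equal candidates split 50/50 within 3 binomial SDs
  set.seed(2)
  n <- 1e5
  idx <- vapply(seq_len(n), function(i)
    phagelattice:::roulette_idx(c(1, 1)), 0L)
  expect_lt(abs(sum(idx == 1L) - n / 2), 3 * sqrt(n * 0.25))

  # chi-squared goodness of fit on a 4-candidate wheel
  w <- c(0.5, 1, 2, 4)
  set.seed(3)
  draws <- vapply(seq_len(n), function(i)
    phagelattice:::roulette_idx(w), 0L)
  gof <- chisq.test(tabulate(draws, 4), p = w / sum(w))
  expect_gt(gof$p.value, 1e-3)

  # all-zero wheel degrades to a uniform choice
  set.seed(4)
  z <- vapply(seq_len(2000), function(i)
    phagelattice:::roulette_idx(c(0, 0)), 0L)
  expect_lt(abs(mean(z == 1L) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("offspring mutation follows the configured gates", {
  reg <- tiny_registry()
  quiet <- bacterial_species("Q")   # both rates zero
  parent <- bacterium(quiet)
  set.seed(1)
  off <- mutate_offspring(parent, reg)
  expect_identical(off[c("antibiotic_resistant", "resisted_phage_phenotypes",
                         "prophages")],
                   parent[c("antibiotic_resistant",
                            "resisted_phage_phenotypes", "prophages")])

  # certain receptor mutation with one available phenotype
  certain <- bacterial_species("C", mu_phage_receptor = 1,
                               phage_resistance_profile = "a")
  set.seed(2)
  off <- mutate_offspring(bacterium(certain), reg)
  expect_setequal(off$resisted_phage_phenotypes, c("a", "b"))

  # Monte-Carlo frequency of antibiotic-resistance mutation at 1e-3
  mut <- bacterial_species("M", mu_antibiotic = 1e-3)
  set.seed(3)
  n <- 1e5
  gained <- sum(vapply(seq_len(n), function(i)
    mutate_offspring(bacterium(mut), reg)$antibiotic_resistant, TRUE))
  expect_lt(abs(gained - n * 1e-3), 3 * sqrt(n * 1e-3 * (1 - 1e-3)))
})

test_that("phage attachment mutation is a uniform switch at the set rate", {
  reg <- tiny_registry(mu_att = 0)
  P <- reg$phages[["P"]]
  expect_identical(mutate_phage_offspring("a", P, reg), "a")
  expect_error(mutate_phage_offspring("zz", P, reg), "unknown")

  P$mu_attachment <- 1
  set.seed(1)
  expect_identical(mutate_phage_offspring("a", P, reg), "b")

  # vectorized burst path: mutant fraction at 1e-4 over 1e6 offspring
  set.seed(2)
  n <- 1e6
  out <- phagelattice:::mutate_phage_pheno_vec(rep(1L, n), 1e-4, 2L)
  mutants <- sum(out != 1L)
  expect_lt(abs(mutants - n * 1e-4), 3 * sqrt(n * 1e-4 * (1 - 1e-4)))
})

test_that("genotype labels are canonical and round-trip", {
  sp <- bacterial_species("S1")
  cell <- bacterium(sp, antibiotic_resistant = TRUE,
                    resisted_phage_phenotypes = c("b", "a"),
                    prophages = list(list(species = "P",
                                          attachment_phenotype = "a")))
  lab <- genotype_label(cell)
  expect_identical(lab, "S1+abR+r(a,b)+lys(P:a)")
  back <- parse_genotype_label(lab)
  expect_identical(back$species, "S1")
  expect_true(back$antibiotic_resistant)
  expect_setequal(back$resisted_phage_phenotypes, c("a", "b"))
  expect_identical(back$prophages[[1]]$species, "P")

  # property: random phenotypes round-trip through the label
  set.seed(9)
  phen <- letters[1:6]
  for (i in 1:25) {
    res <- sample(phen, sample(0:4, 1))
    ab <- sample(c(TRUE, FALSE), 1)
    cell <- bacterium(sp, antibiotic_resistant = ab,
                      resisted_phage_phenotypes = res)
    got <- parse_genotype_label(genotype_label(cell))
    expect_identical(got$antibiotic_resistant, ab)
    expect_setequal(got$resisted_phage_phenotypes, unique(res))
  }
})

test_that("registry validation names the offending entry", {
  b <- list(bacterial_species("S1"))
  p <- list(phage_species("P", "virulent", attachment_phenotype = "a"))
  hr_bad <- matrix(1.5, 1, 1, dimnames = list("a", "S1"))
  expect_error(species_registry(b, p, "a", hr_bad), "host_range\\[a, S1\\]")
  hr <- matrix(1, 1, 1, dimnames = list("a", "S1"))
  expect_error(
    species_registry(list(bacterial_species("S1",
                                            phage_resistance_profile = "z")),
                     p, "a", hr),
    "unknown phenotype")
  expect_error(
    species_registry(b, list(phage_species("P", "temperate",
                                           attachment_phenotype = "a")),
                     "a", hr),
    "lysogeny_curve")
})
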