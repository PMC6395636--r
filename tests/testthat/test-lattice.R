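# Lattice geometry, mixing, virion diffusion and the antibiotic field.

test_that("Moore neighborhoods have the right members under both topologies", {
  cfg_b <- tiny_config(topology = "bounded")
  cfg_t <- tiny_config(topology = "toroidal")

  expect_equal(nrow(neighborhood(c(5, 5), 1, cfg_b)), 8)
  expect_equal(nrow(neighborhood(c(0, 0), 1, cfg_b)), 3)
  expect_equal(nrow(neighborhood(c(0, 0), 1, cfg_t)), 8)
  expect_equal(nrow(neighborhood(c(5, 5), 3, cfg_b)), 48)  # (2r+1)^2 - 1

  # agreement with brute-force enumeration across radii and positions
  for (r in 1:3) for (loc in list(c(0, 0), c(1, 2), c(5, 5), c(9, 9))) {
    for (cfg in list(cfg_b, cfg_t)) {
      got <- neighborhood(loc, r, cfg)
      want <- brute_neighborhood(loc[1], loc[2], r, cfg)
      expect_equal(nrow(got), nrow(want))
      expect_setequal(paste(got[, 1], got[, 2]),
                      paste(want[, 1], want[, 2]))
    }
  }

  # toroidal grids are homogeneous: every radius-r neighborhood is full
  for (r in 1:3) {
    sizes <- vapply(0:99, function(i)
      nrow(neighborhood(c(i %% 10, i %/% 10), r, cfg_t)), 0L)
    expect_true(all(sizes == (2 * r + 1)^2 - 1))
  }

  expect_error(neighborhood(c(10, 0), 1, cfg_b), "outside lattice")
  expect_equal(nrow(neighborhood(c(5, 5), 0, cfg_b)), 0)
})

test_that("antibiotic deployment sets the configured dose pattern", {
  cfg <- tiny_config()
  f <- antibiotic_field(cfg, deployment_mode = "homogeneous", dose = 1)
  f <- deploy_antibiotic(f, cfg)
  expect_equal(total_antibiotic_mass(f), 100)

  set.seed(1)
  f2 <- antibiotic_field(cfg, deployment_mode = "heterogeneous",
                         n_foci = 5, dose = 2)
  f2 <- deploy_antibiotic(f2, cfg)
  expect_equal(sum(f2$conc > 0), 5)
  expect_equal(total_antibiotic_mass(f2), 10)

  expect_error(antibiotic_field(cfg, deployment_mode = "heterogeneous",
                                n_foci = 101), "n_foci")
  expect_error(antibiotic_field(cfg, dose = -1), "dose")
})

test_that("antibiotic diffusion conserves mass and degradation decays it", {
  for (topo in c("toroidal", "bounded")) {
    cfg <- tiny_config(topology = topo)
    f <- antibiotic_field(cfg, degradation_rate = 0, diffusion_fraction = 0.4)
    f$conc[55] <- 7.5   # single focus
    m0 <- total_antibiotic_mass(f)
    for (i in 1:20) f <- update_antibiotic(f, cfg)
    expect_equal(total_antibiotic_mass(f), m0, tolerance = 1e-12)
    expect_true(all(f$conc >= 0))
  }

  # uniform field on a toroidal grid is a diffusion fixed point
  cfg <- tiny_config(topology = "toroidal")
  f <- antibiotic_field(cfg, degradation_rate = 0, diffusion_fraction = 0.3)
  f$conc[] <- 2
  f2 <- update_antibiotic(f, cfg)
  expect_equal(f2$conc, f$conc, tolerance = 1e-12)

  # full decay empties the field in one update
  f$degradation_rate <- 1
  expect_equal(total_antibiotic_mass(update_antibiotic(f, cfg)), 0)
})

test_that("well-mixed randomization permutes agents without changing counts", {
  cfg <- tiny_config(structure = "well_mixed")
  st <- tiny_state(cfg)
  set.seed(5)
  st <- place_bacteria(st, "S1", 30)
  st <- place_bacteria(st, "S2", 20)
  st <- place_phages(st, "P", 60)

  before_b <- sort(table(st$b_species[st$b_species > 0]))
  set.seed(42); m1 <- mix_well(st)
  expect_equal(sort(table(m1$b_species[m1$b_species > 0])), before_b)
  expect_equal(length(m1$p_loc), 60)
  expect_true(max(tabulate(m1$p_loc, 100)) <= cfg$phage_cap_per_location)

  # determinism under a fixed seed
  set.seed(42); m2 <- mix_well(st)
  expect_identical(m1, m2)

  # any non-mixed structure leaves the state untouched
  st_s <- st
  st_s$config$structure <- "structured"
  expect_identical(mix_well(st_s), st_s)

  # a corrupted state fails the consistency assertions
  st_bad <- st
  st_bad$p_species <- st_bad$p_species[-1]  # ragged virion pool
  expect_error(assert_state(st_bad), "consistency")
})

test_that("virion diffusion conserves particles and is uniform over candidates", {
  cfg <- tiny_config(phage_diffusion_radius = 0L, phage_cap_per_location = 10L)
  st <- tiny_state(cfg)
  set.seed(7)
  st <- place_phages(st, "P", 25)
  d0 <- diffuse_phages(st)
  expect_identical(d0$p_loc, st$p_loc)   # radius 0: nothing moves

  cfg1 <- tiny_config(phage_diffusion_radius = 1L,
                      phage_cap_per_location = 200000L)
  st1 <- tiny_state(cfg1)
  n <- 1e5
  st1$p_loc <- rep(55L, n)               # interior origin x=4, y=5
  st1$p_species <- rep(1L, n)
  st1$p_pheno <- rep(1L, n)
  st1$p_age <- integer(n)
  set.seed(11)
  d1 <- diffuse_phages(st1)
  expect_equal(length(d1$p_loc), n)      # conservation
  tab <- tabulate(d1$p_loc, 100)
  cells <- which(tab > 0)
  expect_equal(length(cells), 9)         # self + 8 neighbors
  p <- 1 / 9
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(tab[cells] - n * p) <= sd3))
})

test_that("diffusion respects the per-location virion cap", {
  cfg <- tiny_config(phage_diffusion_radius = 1L, phage_cap_per_location = 3L)
  st <- tiny_state(cfg)
  set.seed(3)
  st <- place_phages(st, "P", 250)  # near saturation: 100 locations x cap 3
  expect_true(max(tabulate(st$p_loc, 100)) <= 3)
  for (i in 1:5) {
    st <- diffuse_phages(st)
    expect_equal(length(st$p_loc), 250)
    expect_no_error(assert_state(st, "diffusion"))
    expect_true(max(tabulate(st$p_loc, 100)) <= 3 + st$cap_overflow)
  }
})
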