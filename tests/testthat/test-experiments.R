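# Ensembles, emergence statistics, estimators, sweeps and RF importance.

test_that("ensembles are seeded deterministically and summarized with CIs", {
  pair <- tiny_pair(n_bact = 40L, n_iterations = 6L)
  ens <- run_ensemble(pair$general, pair$eco, n_replicates = 3,
                      master_seed = 5)
  ens2 <- run_ensemble(pair$general, pair$eco, n_replicates = 3,
                       master_seed = 5)
  expect_identical(ens$trajectories, ens2$trajectories)

  s <- ensemble_summary(ens, "total_bacteria", "summary")
  expect_equal(nrow(s), 7)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))

  # single replicate: degenerate zero-width interval
  one <- run_ensemble(pair$general, pair$eco, n_replicates = 1,
                      master_seed = 1)
  s1 <- ensemble_summary(one, "total_bacteria", "summary")
  expect_equal(s1$lower, s1$mean)
  expect_equal(s1$upper, s1$mean)

  # a stressor-free full lattice is deterministic in its counts:
  # replicates agree and the band collapses
  fixed <- tiny_pair(n_bact = 100L, n_iterations = 4L, basal_death_prob = 0)
  ensf <- run_ensemble(fixed$general, fixed$eco, n_replicates = 3,
                       master_seed = 2)
  sf <- ensemble_summary(ensf, "total_bacteria", "summary")
  expect_true(all(sf$upper - sf$lower == 0))
})

test_that("emergence time is the first threshold crossing", {
  pair <- tiny_pair(n_bact = 10L, n_iterations = 8L, basal_death_prob = 0.05)
  traj <- run_simulation(pair$general, pair$eco, seed = 1)

  # hand-built trajectory: counts 0, 50, 120 cross threshold 100 at t = 2
  fake <- data.frame(iteration = c(0:2), entity_class = "bacterium",
                     label = "X", count = c(0, 50, 120))
  class(fake) <- c("phage_trajectory", "data.frame")
  expect_equal(emergence_time(fake, "X", threshold = 100), 2L)
  expect_equal(emergence_time(fake, "X", threshold = 1), 1L)
  expect_true(is.na(emergence_time(fake, "X", threshold = 200)))
  expect_true(is.na(emergence_time(fake, "never_seen", threshold = 1)))
  expect_error(emergence_time(fake, c("a", "b")), "single")
  expect_error(emergence_time(fake, "X", threshold = 0), "threshold")

  expect_equal(emergence_time(traj, "S1", threshold = 1,
                              entity_class = "bacterium"), 0L)
})

test_that("emergence CV uses detected replicates only and is scale invariant", {
  mk_traj <- function(t_cross) {
    df <- data.frame(iteration = 0:30, entity_class = "bacterium",
                     label = "X",
                     count = ifelse(0:30 >= t_cross, 150, 0))
    class(df) <- c("phage_trajectory", "data.frame")
    df
  }
  ens <- list(trajectories = list(mk_traj(10), mk_traj(20), mk_traj(99)))
  class(ens) <- "phage_ensemble"
  out <- emergence_cv(ens, "X", threshold = 100)
  expect_equal(out$n_detected, 2)
  expect_equal(out$cv, sd(c(10, 20)) / 15)         # = (5 sqrt 2)/15 ~ 0.4714
  expect_equal(out$cv, 0.4714, tolerance = 1e-4)

  # identical detection everywhere: CV 0
  same <- list(trajectories = list(mk_traj(7), mk_traj(7), mk_traj(7)))
  class(same) <- "phage_ensemble"
  expect_equal(emergence_cv(same, "X", threshold = 100)$cv, 0)

  # no detections: NA with a zero count
  none <- list(trajectories = list(mk_traj(99), mk_traj(99)))
  class(none) <- "phage_ensemble"
  out0 <- emergence_cv(none, "X", threshold = 100)
  expect_true(is.na(out0$cv))
  expect_equal(out0$n_detected, 0)

  # scale invariance: multiplying all detection times by c leaves CV fixed
  scaled <- list(trajectories = list(mk_traj(9), mk_traj(18), mk_traj(27)))
  class(scaled) <- "phage_ensemble"
  base <- list(trajectories = list(mk_traj(3), mk_traj(6), mk_traj(9)))
  class(base) <- "phage_ensemble"
  expect_equal(emergence_cv(scaled, "X", 100)$cv,
               emergence_cv(base, "X", 100)$cv)
})

test_that("the emergence contingency test equals the Yates formula", {
  # the worked example from the arms-race emergence table
  out <- emergence_contingency(18, 30, 30, 30)
  expect_equal(out$statistic, 12.6, tolerance = 0.05 / 12.6)
  expect_equal(out$p_value, 4e-4, tolerance = 0.1)

  expect_equal(emergence_contingency(30, 30, 30, 30)$statistic, 0)
  expect_equal(emergence_contingency(30, 30, 30, 30)$p_value, 1)
  expect_equal(emergence_contingency(15, 30, 15, 30)$statistic, 0)

  # random tables vs a direct evaluation of the corrected formula
  set.seed(13)
  for (i in 1:400) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if ((k1 + k2) == 0 || (k1 + k2) == (n1 + n2)) next  # empty margin
    got <- emergence_contingency(k1, n1, k2, n2)$statistic
    expect_equal(got, yates_chisq(k1, n1 - k1, k2, n2 - k2),
                 tolerance = 1e-10)
  }

  # zero column margins force identical proportions: statistic 0
  expect_equal(emergence_contingency(0, 30, 0, 30)$statistic, 0)
  expect_error(emergence_contingency(31, 30, 1, 30), "0 <= k <= n")
})

test_that("the adsorption estimator recovers known decline constants", {
  # synthetic trajectory: pure exponential decline P_t = P0 exp(-k t) with
  # one host per location-iteration and no decay; slope must recover k
  k <- 0.37
  mk <- function() {
    t <- 0:8
    df <- rbind(
      data.frame(iteration = t, entity_class = "summary",
                 label = "total_free_virions",
                 count = 1e6 * exp(-k * t)),
      data.frame(iteration = t, entity_class = "summary",
                 label = "total_bacteria", count = 1))
    class(df) <- c("phage_trajectory", "data.frame")
    df
  }
  ens <- list(trajectories = list(mk()),
              eco = list(phages = list(list(species = list(decay_prob = 0)))))
  class(ens) <- "phage_ensemble"
  est <- estimate_population_adsorption(ens, window = 0:8)
  expect_equal(est$rate, k, tolerance = 0.01)

  # live simulations: zero individual adsorption gives a ~zero rate, and the
  # estimated rate is monotone in the configured adsorption probability
  rate_for <- function(ads, seeds) {
    pair <- tiny_pair(n_bact = 80L, n_phage = 300L, n_iterations = 8L,
                      basal_death_prob = 0)
    pair$eco$phages[[1]]$species$adsorption_prob <- ads
    pair$eco$phages[[1]]$species$burst_size <- 0L
    pair$general$phage_cap_per_location <- 500L
    ens <- run_ensemble(pair$general, pair$eco, n_replicates = seeds,
                        master_seed = 99)
    estimate_population_adsorption(ens, window = 0:6)$rate
  }
  expect_lt(rate_for(0, 3), 1e-3)
  lo <- rate_for(0.2, 5)
  hi <- rate_for(0.8, 5)
  expect_gt(hi, lo)
})

test_that("invasion metrics partition the lattice and expose the response", {
  pair <- scenario("fig5_invasion",
                   overrides = list("general.width" = 20,
                                    "general.height" = 20,
                                    "general.n_iterations" = 16))
  pair$eco$bacteria[[1]]$count <- 300L  # keep the 1:10 inoculum ratio
  pair$eco$bacteria[[2]]$count <- 30L
  traj <- run_simulation(pair$general, pair$eco, seed = 6)
  im <- invasion_metrics(traj)
  expect_equal(im$invader_freq[1] / im$resident_sensitive_freq[1], 1 / 10)
  sums <- im$invader_freq + im$resident_sensitive_freq +
    im$resident_lysogen_freq + im$empty_freq
  expect_equal(sums, rep(1, nrow(im)))
  expect_false(is.na(attr(im, "response")))

  # without induction and without free phage no resident is ever lysogenized
  pair0 <- scenario("fig5_invasion",
                    overrides = list("general.width" = 20,
                                     "general.height" = 20,
                                     "general.n_iterations" = 16,
                                     "eco.bacterium.S.count" = 300,
                                     "eco.bacterium.L.count" = 30,
                                     "eco.phage.P.induction_prob" = 0))
  traj0 <- run_simulation(pair0$general, pair0$eco, seed = 6)
  im0 <- invasion_metrics(traj0)
  expect_true(all(im0$resident_lysogen_freq == 0))
  expect_true(all(im0$free_phage == 0))
})

test_that("the quadratic early-growth fit is exact on polynomial data", {
  mk_ens <- function(f, reps = 3, n_loc = 400) {
    trajs <- lapply(seq_len(reps), function(r) {
      t <- 0:15
      df <- rbind(
        data.frame(iteration = t, entity_class = "bacterium",
                   label = "S+lys(P:a)", count = f(t)),
        data.frame(iteration = t, entity_class = "bacterium",
                   label = "S", count = 10),
        data.frame(iteration = t, entity_class = "bacterium",
                   label = "L+lys(P:a)", count = 5),
        data.frame(iteration = t, entity_class = "summary",
                   label = "total_free_virions", count = 0))
      class(df) <- c("phage_trajectory", "data.frame")
      attr(df, "meta") <- list(n_locations = n_loc)
      df
    })
    structure(list(trajectories = trajs), class = "phage_ensemble")
  }
  ens_a <- mk_ens(function(t) 2 * t^2)
  ens_b <- mk_ens(function(t) 2 * t^2 + 3 * t)
  fit <- early_lysogenization_fit(ens_a, ens_b, window = 10)
  expect_equal(fit$coef_a[3], 2, tolerance = 1e-8)
  expect_equal(fit$coef_a[2], 0, tolerance = 1e-8)
  expect_equal(fit$coef_b[3], 2, tolerance = 1e-8)
  expect_equal(fit$coef_b[2], 3, tolerance = 1e-8)

  # identical generating processes: the trend-difference test stays null
  set.seed(21)
  null_p <- replicate(20, {
    noisy <- function(t) 5 * t + stats::rnorm(length(t), 0, 3)
    fit0 <- early_lysogenization_fit(mk_ens(noisy), mk_ens(noisy),
                                     window = 10)
    fit0$p_value
  })
  expect_gte(sum(null_p > 0.05), 17)   # ~19/20 expected at the 5% level

  expect_error(early_lysogenization_fit(ens_a, ens_b, window = 40),
               "window longer")
})

test_that("sweep designs are deterministic with an independent dummy", {
  d1 <- sweep_design(n_combinations = 500, master_seed = 3)
  d2 <- sweep_design(n_combinations = 500, master_seed = 3)
  expect_identical(d1, d2)
  expect_true("dummy" %in% names(d1))
  expect_equal(nrow(d1), 500)
  # rank correlation between the dummy and every numeric parameter is noise
  for (col in names(d1)) {
    if (col == "dummy" || !is.numeric(d1[[col]])) next
    rho <- abs(cor(d1[[col]], d1$dummy, method = "spearman"))
    expect_lt(rho, 0.1)
  }
  expect_error(sweep_design(ranges = list()), "nonempty")
})

test_that("small simulated sweeps have the declared shape and reproduce", {
  ranges <- list(
    "eco.phage.P.burst_size" = list(min = 20, max = 80, integer = TRUE),
    "eco.phage.P.lysogeny_curve" =
      list(values = c("Lysogeny1", "Lysogeny3")))
  base_ov <- list("general.width" = 15, "general.height" = 15,
                  "general.n_iterations" = 16,
                  "eco.bacterium.S.count" = 150, "eco.bacterium.L.count" = 15)
  tab <- sample_sweep(ranges, n_combinations = 6, repeats = 2,
                      master_seed = 4, base_overrides = base_ov)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("dummy", "response") %in% names(tab)))
  expect_true(all(tab$response >= 0))
  tab2 <- sample_sweep(ranges, n_combinations = 6, repeats = 2,
                       master_seed = 4, base_overrides = base_ov)
  expect_identical(tab, tab2)
})

test_that("random-forest importance finds planted signals above the dummy", {
  set.seed(31)
  n <- 300
  mk_table <- function() {
    tab <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n),
                      dummy = sample(1:3, n, replace = TRUE))
    tab$response <- tab$x1 + rnorm(n, 0, 0.05)
    tab
  }
  rep <- permutation_importance(mk_table(), n_trees = 500)
  expect_identical(rep$importance$parameter[1], "x1")
  expect_true(rep$importance$above_noise_floor[1])
  expect_false(any(rep$importance$above_noise_floor[
    rep$importance$parameter == "dummy"]))

  # planted-driver recovery rate across reseeded tables
  hits <- sum(replicate(20, {
    r <- permutation_importance(mk_table(), n_trees = 300)
    r$importance$parameter[1] == "x1"
  }))
  expect_gte(hits, 19)

  # shuffled response: nothing beats noise by a wide margin
  set.seed(32)
  tab <- mk_table()
  tab$response <- sample(tab$response)
  r0 <- permutation_importance(tab, n_trees = 500)
  # nothing retains the planted signal strength once the response is shuffled
  expect_lt(max(r0$importance$inc_mse_pct),
            rep$importance$inc_mse_pct[1] / 2)

  # degenerate constant response
  tab$response <- 1
  expect_warning(rc <- permutation_importance(tab, n_trees = 100),
                 "constant")
  expect_true(all(rc$importance$inc_mse_pct == 0))

  expect_error(permutation_importance(mk_table()[1:10, ]), "at least")
})
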