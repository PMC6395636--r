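# Replicate ensembles, emergence statistics, population-level estimators and
# the random-forest parameter-importance harness.

#' Run a replicate ensemble
#'
#' Runs `n_replicates` seeded trajectories of one configuration pair.
#' Per-replicate seeds are drawn from a stream seeded with `master_seed`, so
#' the whole ensemble is a pure function of `(config, master_seed)`.
#'
#' @param general,eco A configuration pair (see [scenario()] or
#'   [parse_configs()]).
#' @param n_replicates Number of replicate simulations (>= 1).
#' @param master_seed Integer master seed.
#' @param validate Passed to [run_simulation()].
#' @return An object of class `phage_ensemble`: a list with `trajectories`,
#'   `seeds`, `general` and `eco`.
#' @export
run_ensemble <- function(general, eco, n_replicates, master_seed,
                         validate = FALSE) {
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  trajectories <- lapply(seeds, function(s)
    run_simulation(general, eco, seed = s, validate = validate))
  structure(list(trajectories = trajectories, seeds = seeds,
                 general = general, eco = eco),
            class = "phage_ensemble")
}

#' Ensemble mean and confidence band for one label
#'
#' Per-iteration mean and normal-approximation 95% confidence interval of a
#' counted label across the replicates. With a single replicate (or zero
#' variance) the interval has width 0.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param label Counted label.
#' @param entity_class Entity class of the label.
#' @return A data frame with `iteration`, `mean`, `lower`, `upper`.
#' @export
ensemble_summary <- function(ensemble, label, entity_class = "bacterium") {
  series <- vapply(ensemble$trajectories, traj_counts,
                   numeric(max(ensemble$trajectories[[1L]]$iteration) + 1L),
                   label = label, entity_class = entity_class)
  series <- matrix(series, ncol = length(ensemble$trajectories))
  n <- ncol(series)
  m <- rowMeans(series)
  se <- if (n > 1L) apply(series, 1L, stats::sd) / sqrt(n) else numeric(nrow(series))
  data.frame(iteration = seq_len(nrow(series)) - 1L, mean = m,
             lower = m - 1.96 * se, upper = m + 1.96 * se)
}

#' Emergence time of a genotype or phenotype
#'
#' First iteration at which the label's count reaches `threshold`
#' individuals; `NA` when the threshold is never reached by the final
#' iteration (including labels that never appear at all, e.g. mutants that
#' never arose).
#'
#' @param trajectory A `phage_trajectory`.
#' @param label Genotype or phage-phenotype label.
#' @param threshold Detection threshold (>= 1 individuals).
#' @param entity_class Entity class of the label.
#' @return Integer iteration or `NA`.
#' @export
emergence_time <- function(trajectory, label, threshold = 100,
                           entity_class = "bacterium") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a single non-empty string")
  if (threshold < 1) stop("threshold must be >= 1")
  x <- traj_counts(trajectory, label, entity_class)
  hit <- which(x >= threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(names(x)[hit[1L]])
}

#' Emergence-time variability across an ensemble
#'
#' Coefficient of variation (sample SD / mean) of the emergence times,
#' computed over the replicates where the label was detected; undetected
#' replicates are excluded and reported separately.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param label Genotype or phage-phenotype label.
#' @param threshold Detection threshold.
#' @param entity_class Entity class of the label.
#' @return A list with `cv` (`NA` when fewer than 2 replicates detected the
#'   label), `n_detected`, `n_replicates` and the detected `times`.
#' @export
emergence_cv <- function(ensemble, label, threshold = 100,
                         entity_class = "bacterium") {
  times <- vapply(ensemble$trajectories, emergence_time, 0L,
                  label = label, threshold = threshold,
                  entity_class = entity_class)
  det <- times[!is.na(times)]
  cv <- if (length(det) >= 2L && mean(det) > 0) stats::sd(det) / mean(det)
  else NA_real_
  list(cv = cv, n_detected = length(det),
       n_replicates = length(times), times = det)
}

#' Chi-squared contingency test on emergence fractions
#'
#' Yates-corrected 2x2 chi-squared test comparing the number of replicates
#' in which a genotype emerged between two conditions
#' (`[[k1, n1-k1], [k2, n2-k2]]`, 1 degree of freedom).
#'
#' @param k1,n1 Detections and replicates in condition 1.
#' @param k2,n2 Detections and replicates in condition 2.
#' @return A list with `statistic` and `p_value`.
#' @export
emergence_contingency <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("replicate counts must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("detections must satisfy 0 <= k <= n")
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(colSums(tab) == 0)) {
    # a zero column margin forces identical proportions (all detected or
    # none detected in both conditions): the corrected statistic is 0
    return(list(statistic = 0, p_value = 1))
  }
  ht <- suppressWarnings(stats::prop.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Population-level adsorption rate from ensemble dynamics
#'
#' Converts individual-level adsorption into the population-level rate an
#' experimentalist would measure, by following the early decline of the free
#' virion pool. For each trajectory the log free-virion count, corrected for
#' the known per-iteration decay hazard, is regressed on the cumulative host
#' exposure (the running sum of host counts); the negative slope estimates
#' the per-host per-iteration adsorption rate.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param window Iterations of the early decline to use (default 0..5).
#' @param min_points Minimum usable (positive-count) points per trajectory.
#' @param decay_prob Known per-iteration virion decay probability (defaults
#'   to the configured value of the first phage species).
#' @return A list with `rate` (ensemble mean), `per_trajectory` rates, and
#'   the number of trajectories used.
#' @export
estimate_population_adsorption <- function(ensemble, window = 0:5,
                                           min_points = 3L,
                                           decay_prob = NULL) {
  if (is.null(decay_prob)) {
    ph <- ensemble$eco$phages
    if (!length(ph)) stop("ensemble has no phage species")
    decay_prob <- ph[[1L]]$species$decay_prob
  }
  rates <- vapply(ensemble$trajectories, function(traj) {
    adsorption_rate_one(traj, window, min_points, decay_prob)
  }, 0)
  rates <- rates[!is.na(rates)]
  if (!length(rates)) stop("no trajectory had a usable decline window")
  list(rate = mean(rates), per_trajectory = rates, n_used = length(rates))
}

adsorption_rate_one <- function(traj, window, min_points, decay_prob) {
  phage <- traj_counts(traj, "total_free_virions", "summary")[
    as.character(window)]
  hosts <- traj_counts(traj, "total_bacteria", "summary")[as.character(window)]
  ok <- !is.na(phage) & phage > 0
  # shrink the window to the leading run of positive virion counts
  if (any(!ok)) {
    lead <- which(!ok)[1L] - 1L
    if (lead < min_points) return(NA_real_)
    phage <- phage[seq_len(lead)]; hosts <- hosts[seq_len(lead)]
  }
  if (length(phage) < min_points) return(NA_real_)
  t_idx <- seq_along(phage) - 1L
  y <- log(phage) - t_idx * log(1 - decay_prob)
  exposure <- cumsum(c(0, hosts[-length(hosts)]))
  fit <- stats::lm(y ~ exposure)
  max(0, -unname(stats::coef(fit)[2L]))
}

#' Invasion subpopulation dynamics
#'
#' Splits an invasion trajectory into the three bacterial subpopulations -
#' invading lysogens, sensitive residents and lysogenized residents - as
#' frequencies of lattice capacity, plus the free-phage count. Also exposes
#' the standard response variable: the lysogenized-resident count at the
#' response iteration.
#'
#' @param trajectory A `phage_trajectory` from an invasion scenario.
#' @param invader_species,resident_species Species names (defaults match the
#'   invasion presets).
#' @param response_iteration Iteration of the response variable (default
#'   15).
#' @return A data frame with `iteration`, `invader_freq`,
#'   `resident_sensitive_freq`, `resident_lysogen_freq`, `free_phage`,
#'   `empty_freq`; the response count is in attribute `response`.
#' @export
invasion_metrics <- function(trajectory, invader_species = "L",
                             resident_species = "S",
                             response_iteration = 15L) {
  meta <- attr(trajectory, "meta")
  if (is.null(meta$n_locations)) stop("trajectory lacks lattice metadata")
  labels <- traj_labels(trajectory, "bacterium")
  parse_sp <- vapply(labels, function(l) parse_genotype_label(l)$species, "")
  is_lys <- vapply(labels, function(l)
    length(parse_genotype_label(l)$prophages) > 0, TRUE)
  if (!any(parse_sp == invader_species) && !any(parse_sp == resident_species))
    stop("trajectory contains neither ", invader_species, " nor ",
         resident_species)
  n_it <- max(trajectory$iteration) + 1L
  sum_counts <- function(labs) {
    if (!length(labs)) return(numeric(n_it))
    rowSums(vapply(labs, function(l)
      traj_counts(trajectory, l, "bacterium"), numeric(n_it)))
  }
  inv <- sum_counts(labels[parse_sp == invader_species])
  res_sens <- sum_counts(labels[parse_sp == resident_species & !is_lys])
  res_lys <- sum_counts(labels[parse_sp == resident_species & is_lys])
  N <- meta$n_locations
  out <- data.frame(
    iteration = seq_len(n_it) - 1L,
    invader_freq = inv / N,
    resident_sensitive_freq = res_sens / N,
    resident_lysogen_freq = res_lys / N,
    free_phage = traj_counts(trajectory, "total_free_virions", "summary"),
    empty_freq = 1 - (inv + res_sens + res_lys) / N)
  ri <- as.integer(response_iteration)
  attr(out, "response") <-
    if (ri < n_it) res_lys[ri + 1L] else NA_real_
  out
}

#' Early lysogenization fits and environment comparison
#'
#' Fits a quadratic polynomial of the lysogenized-resident count against
#' iteration over the first `window` iterations, separately for two
#' ensembles (pooling replicate points), and tests whether the time trend
#' differs between environments through the joint significance of the
#' environment x time interaction terms in the pooled quadratic regression
#' (an analysis-of-covariance analogue).
#'
#' @param ensemble_a,ensemble_b Two [run_ensemble()] results tracking
#'   lysogenized residents.
#' @param window Number of initial iterations to fit (uses iterations
#'   0..window).
#' @param invader_species,resident_species Passed to [invasion_metrics()].
#' @return A list with `coef_a`, `coef_b` (intercept, linear, quadratic),
#'   `f_statistic`, `p_value` and the pooled model.
#' @export
early_lysogenization_fit <- function(ensemble_a, ensemble_b, window = 10L,
                                     invader_species = "L",
                                     resident_species = "S") {
  get_points <- function(ensemble, env_label) {
    do.call(rbind, lapply(ensemble$trajectories, function(traj) {
      n_it <- max(traj$iteration)
      if (window > n_it) stop("window longer than trajectory")
      im <- invasion_metrics(traj, invader_species, resident_species)
      data.frame(iter = 0:window,
                 count = im$resident_lysogen_freq[1:(window + 1L)] *
                   attr(traj, "meta")$n_locations,
                 env = env_label)
    }))
  }
  pts <- rbind(get_points(ensemble_a, "a"), get_points(ensemble_b, "b"))
  fit_one <- function(env_label) {
    d <- pts[pts$env == env_label, ]
    unname(stats::coef(stats::lm(count ~ iter + I(iter^2), data = d)))
  }
  coef_a <- fit_one("a"); coef_b <- fit_one("b")
  pts$env <- factor(pts$env)
  full <- stats::lm(count ~ env * (iter + I(iter^2)), data = pts)
  null <- stats::lm(count ~ env + iter + I(iter^2), data = pts)
  an <- stats::anova(null, full)
  list(coef_a = coef_a, coef_b = coef_b,
       f_statistic = an$F[2L], p_value = an$`Pr(>F)`[2L], model = full)
}

# parameter sweeps and random-forest importance --------------------------------

#' Default sweep parameter ranges
#'
#' The parameter space sampled by [sample_sweep()] for the invasion
#' response: each entry declares either a uniform interval
#' (`list(min=, max=)`) or a finite set (`list(values=)`), keyed by the
#' override path it controls.
#'
#' @return A named list of sampling laws.
#' @export
sweep_parameter_ranges <- function() {
  list(
    "eco.phage.P.burst_size" = list(min = 10, max = 150, integer = TRUE),
    "eco.phage.P.adsorption_prob" = list(min = 0.1, max = 1),
    "eco.phage.P.decay_prob" = list(min = 0.01, max = 0.3),
    "eco.phage.P.induction_prob" = list(min = 0.001, max = 0.05),
    "eco.phage.P.lysogeny_curve" =
      list(values = c("Lysogeny1", "Lysogeny2", "Lysogeny3")),
    "general.structure" =
      list(values = c("well_mixed", "semi_structured", "structured")),
    "general.phage_diffusion_radius" = list(values = c(1, 2, 3, 5)))
}

#' Sample a sweep design
#'
#' Draws `n_combinations` random parameter combinations from the declared
#' ranges and appends the dummy parameter: a uniform random choice among
#' {1, 2, 3}, independent of everything else by construction, which later
#' serves as the noise floor of the importance analysis.
#'
#' @param ranges Named list of sampling laws (see
#'   [sweep_parameter_ranges()]).
#' @param n_combinations Number of sampled points.
#' @param master_seed Integer seed.
#' @return A data frame with one column per parameter plus `dummy`.
#' @export
sweep_design <- function(ranges = sweep_parameter_ranges(),
                         n_combinations = 100L, master_seed = 1L) {
  if (!length(ranges)) stop("ranges must be nonempty")
  set.seed(as.integer(master_seed))
  cols <- lapply(ranges, function(r) {
    if (!is.null(r$values)) {
      r$values[sample.int(length(r$values), n_combinations, replace = TRUE)]
    } else {
      x <- stats::runif(n_combinations, r$min, r$max)
      if (isTRUE(r$integer)) round(x) else x
    }
  })
  design <- as.data.frame(cols, optional = TRUE)
  names(design) <- names(ranges)
  design$dummy <- sample.int(3L, n_combinations, replace = TRUE)
  design
}

#' Run a parameter sweep
#'
#' Samples a [sweep_design()] and, for each combination, runs `repeats`
#' seeded replicates of the invasion scenario with the combination applied
#' as overrides; the response is the mean lysogenized-resident count at the
#' response iteration.
#'
#' @param ranges Named list of sampling laws.
#' @param n_combinations Number of sampled combinations.
#' @param repeats Simulated repeats per combination.
#' @param master_seed Integer seed controlling both the design and the runs.
#' @param base_scenario Scenario preset the overrides modify.
#' @param base_overrides Overrides applied to every combination (e.g. a
#'   smaller lattice for quick sweeps).
#' @param response_iteration Iteration of the response variable.
#' @return A `sweep_table` data frame: the design columns, `dummy` and
#'   `response`.
#' @export
sample_sweep <- function(ranges = sweep_parameter_ranges(),
                         n_combinations = 100L, repeats = 5L,
                         master_seed = 1L,
                         base_scenario = "fig5_invasion",
                         base_overrides = list(),
                         response_iteration = 15L) {
  design <- sweep_design(ranges, n_combinations, master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, n_combinations * repeats),
                  nrow = n_combinations)
  response <- numeric(n_combinations)
  for (i in seq_len(n_combinations)) {
    ov <- as.list(design[i, setdiff(names(design), "dummy"), drop = FALSE])
    ov <- utils::modifyList(as.list(base_overrides), ov)
    pair <- scenario(base_scenario, overrides = ov)
    vals <- vapply(seq_len(repeats), function(j) {
      traj <- run_simulation(pair$general, pair$eco, seed = seeds[i, j])
      attr(invasion_metrics(traj, response_iteration = response_iteration),
           "response")
    }, 0)
    response[i] <- mean(vals)
  }
  design$response <- response
  class(design) <- c("sweep_table", "data.frame")
  design
}

#' Random-forest permutation importance with a dummy noise floor
#'
#' Fits a random-forest regressor of the response on every parameter
#' including the dummy, and reports each parameter's permutation importance:
#' the percentage increase in out-of-bag mean squared error when that
#' column's values are randomly permuted (%IncMSE). The dummy parameter's
#' importance is the noise floor; parameters at or below it are flagged
#' non-important.
#'
#' @param table A `sweep_table` from [sample_sweep()] (or any data frame
#'   with predictor columns, a `dummy` column and a `response` column).
#' @param n_trees Number of trees (default 10000).
#' @param min_rows Minimum rows required (default 50).
#' @return An object of class `importance_report`: a list with `importance`
#'   (data frame of parameter, inc_mse_pct, rank, above_noise_floor) and
#'   `dummy_importance`.
#' @export
permutation_importance <- function(table, n_trees = 10000L, min_rows = 50L) {
  if (!("response" %in% names(table)) || !("dummy" %in% names(table)))
    stop("table must contain 'dummy' and 'response' columns")
  if (nrow(table) < min_rows)
    stop("table must have at least ", min_rows, " rows")
  y <- table$response
  x <- table[, setdiff(names(table), "response"), drop = FALSE]
  for (j in seq_along(x)) if (is.character(x[[j]])) x[[j]] <- factor(x[[j]])
  if (stats::var(y) == 0) {
    warning("constant response: all importances reported as 0")
    imp <- data.frame(parameter = names(x),
                      inc_mse_pct = 0, rank = NA_integer_,
                      above_noise_floor = FALSE)
    return(structure(list(importance = imp, dummy_importance = 0),
                     class = "importance_report"))
  }
  rf <- randomForest::randomForest(x, y, ntree = as.integer(n_trees),
                                   importance = TRUE)
  raw <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1L]
  dummy_imp <- unname(raw[["dummy"]])
  imp <- data.frame(parameter = names(raw), inc_mse_pct = unname(raw))
  imp <- imp[order(-imp$inc_mse_pct), ]
  imp$rank <- seq_len(nrow(imp))
  imp$above_noise_floor <- imp$inc_mse_pct > dummy_imp &
    imp$parameter != "dummy"
  rownames(imp) <- NULL
  structure(list(importance = imp, dummy_importance = dummy_imp, forest = rf),
            class = "importance_report")
}
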