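# The per-iteration update cycle, free-space reproduction and seeded runs.

#' Schedule configuration
#'
#' @param n_iterations Number of iterations to run (>= 0; 0 records only the
#'   initial state).
#' @param antibiotic_application_iteration Iteration at which the antibiotic
#'   dose is deployed (`NULL` for never). Must be `<= n_iterations`.
#' @param repeat_doses_every Redeploy every this many iterations after the
#'   first application (`NULL` for a single dose).
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_iterations = 80L,
                            antibiotic_application_iteration = NULL,
                            repeat_doses_every = NULL) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 0L)
    stop("n_iterations must be an integer >= 0")
  if (!is.null(antibiotic_application_iteration)) {
    antibiotic_application_iteration <-
      as.integer(antibiotic_application_iteration)
    if (antibiotic_application_iteration < 1L ||
        antibiotic_application_iteration > n_iterations)
      stop("antibiotic_application_iteration must be within 1..n_iterations")
  }
  if (!is.null(repeat_doses_every)) {
    repeat_doses_every <- as.integer(repeat_doses_every)
    if (repeat_doses_every < 1L) stop("repeat_doses_every must be >= 1")
  }
  structure(list(n_iterations = n_iterations,
                 antibiotic_application_iteration =
                   antibiotic_application_iteration,
                 repeat_doses_every = repeat_doses_every),
            class = "schedule_config")
}

# radius of the parental competition neighborhood for a free location
competition_radius <- function(config) {
  switch(config$structure,
         structured = 1L,
         semi_structured = config$reproduction_radius,
         well_mixed = 1L)  # global access is provided by the mixing phase
}

# fitness of every occupied location (0 where empty)
fitness_field <- function(state) {
  reg <- state$registry
  occ <- state$b_species != 0L
  f <- numeric(length(state$b_species))
  sp <- state$b_species[occ]
  fv <- reg$bs_growth[sp]
  fv <- fv * ifelse(state$b_abres[occ], 1 - reg$bs_cost_ab[sp], 1)
  nres <- bit_count(state$b_phres[occ])
  fv <- fv * (1 - reg$bs_cost_ph[sp])^nres
  f[occ] <- fv
  f
}

#' Fill free space by local competition
#'
#' Free locations are visited in uniformly random order. For each, the live
#' bacteria within the competition radius (radius 1 under full structure or
#' after well-mixed randomization; `reproduction_radius` under
#' semi-structure) compete through fitness-proportionate selection; the
#' winner's offspring (phenotype and prophages copied from the parent) is
#' placed in the free location; resistance mutation happens in the
#' subsequent [mutation_pass()]. A cell divides at most once per iteration, and only
#' cells alive at the start of the pass can parent, so the population can at
#' most double within one iteration; which cells reproduce still depends on
#' where space frees up, keeping reproduction asynchronous across the
#' population.
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
reproduce_into_free_space <- function(state) {
  free <- which(state$b_species == 0L)
  if (!length(free)) return(state)
  if (!any(state$b_species != 0L)) return(state)
  reg <- state$registry
  N <- n_locations(state$config)
  r <- competition_radius(state$config)
  nbr <- state_nbr(state, r)
  fit <- fitness_field(state)
  eligible <- state$b_species != 0L   # one division per cell per iteration
  # eligibility only shrinks during the pass, so free locations with no
  # eligible neighbor now can never be filled this iteration
  reachable <- neighbor_sum(as.numeric(eligible), nbr)[free] > 0
  free <- free[reachable]
  if (!length(free)) return(state)
  order_free <- if (length(free) > 1L) sample(free) else free
  for (i in order_free) {
    nb <- nbr[i, ]
    nb <- nb[nb <= N]
    cand <- nb[eligible[nb]]
    if (!length(cand)) next
    j <- if (length(cand) == 1L) cand else cand[roulette_idx(fit[cand])]
    eligible[j] <- FALSE
    state$b_species[i] <- state$b_species[j]
    state$b_abres[i] <- state$b_abres[j]
    state$b_phres[i] <- state$b_phres[j]
    state$b_proph[i] <- state$b_proph[j]
    state$b_age[i] <- 0L
    state$tally["births"] <- state$tally["births"] + 1
  }
  state
}

#' Resistance mutation pass
#'
#' Applies the per-cell per-iteration mutation probabilities to every living
#' bacterium (newborns included): with probability `mu_antibiotic` a
#' sensitive cell gains antibiotic resistance, and independently with
#' probability `mu_phage_receptor` a cell gains resistance to one uniformly
#' chosen attachment phenotype it does not already resist. This realizes
#' mutant emergence at the configured rate per cell per iteration.
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
mutation_pass <- function(state) {
  reg <- state$registry
  occ <- which(state$b_species != 0L)
  if (!length(occ)) return(state)
  sp <- state$b_species[occ]
  mu_ab <- reg$bs_mu_ab[sp]
  if (any(mu_ab > 0)) {
    hit <- !state$b_abres[occ] & stats::runif(length(occ)) < mu_ab
    if (any(hit)) {
      state$b_abres[occ[hit]] <- TRUE
      state$tally["mutations_antibiotic"] <-
        state$tally["mutations_antibiotic"] + sum(hit)
    }
  }
  mu_ph <- reg$bs_mu_ph[sp]
  if (any(mu_ph > 0)) {
    n_pheno <- reg$n_pheno
    full_mask <- mask_from_bits(seq_len(n_pheno))
    hit <- which(state$b_phres[occ] != full_mask &
                   stats::runif(length(occ)) < mu_ph)
    for (k in hit) {
      i <- occ[k]
      open <- which(!has_bit(state$b_phres[i], seq_len(n_pheno)))
      state$b_phres[i] <- set_bit(state$b_phres[i],
                                  open[sample.int(length(open), 1L)])
    }
    state$tally["mutations_phage"] <-
      state$tally["mutations_phage"] + length(hit)
  }
  state
}

antibiotic_due <- function(schedule, iteration) {
  app <- schedule$antibiotic_application_iteration
  if (is.null(app)) return(FALSE)
  if (iteration == app) return(TRUE)
  rep_every <- schedule$repeat_doses_every
  !is.null(rep_every) && iteration > app &&
    (iteration - app) %% rep_every == 0L
}

#' Advance the simulation by one iteration
#'
#' Applies the phases of the update cycle in fixed order: (1) antibiotic
#' deployment (if scheduled) and diffusion/degradation; (2) well-mixed
#' randomization or virion diffusion; (3) virion decay; (4) the infection
#' pass; (5) prophage induction; (6) resolution of all pending lyses (deaths,
#' bursts, local dispersal); (7) basal and antibiotic mortality; (8) filling
#' of free space by reproduction; (9) the per-cell resistance mutation pass.
#' The iteration counter then increments; the
#' caller records the trajectory row and resets the event tallies.
#'
#' @param state A [simulation_state()].
#' @param schedule A [schedule_config()].
#' @param validate Assert occupancy/capacity invariants after every phase
#'   (used by tests; off by default for speed).
#' @return The state after one full iteration.
#' @export
simulation_step <- function(state, schedule, validate = FALSE) {
  it <- state$iter + 1L
  chk <- function(s, w) if (validate) assert_state(s, w) else s

  if (antibiotic_due(schedule, it))
    state$field <- deploy_antibiotic(state$field, state$config)
  state$field <- update_antibiotic(state$field, state$config,
                                   nbr = state_nbr(state, 1L))
  state <- chk(state, "antibiotic")

  if (state$config$structure == "well_mixed") {
    state <- mix_well(state)
  } else {
    state <- diffuse_phages(state)
  }
  state <- chk(state, "mixing")

  state <- chk(decay_free_phages(state), "decay")
  state <- chk(infection_pass(state), "infection")
  state <- chk(induce_prophages(state), "induction")
  state <- chk(resolve_lyses(state), "lysis")
  state <- chk(apply_mortality(state), "mortality")
  state <- chk(reproduce_into_free_space(state), "reproduction")
  state <- chk(mutation_pass(state), "mutation")

  state$b_age[state$b_species != 0L] <- state$b_age[state$b_species != 0L] + 1L
  state$iter <- it
  state
}

# trajectory recording --------------------------------------------------------

# genotype label for each occupied location, with a memoising cache keyed on
# the packed phenotype
genotype_labels_for <- function(state, idx, cache) {
  reg <- state$registry
  key <- paste(state$b_species[idx], state$b_abres[idx],
               state$b_phres[idx], state$b_proph[idx])
  uk <- which(!duplicated(key))
  ulabs <- vapply(uk, function(u) {
    k <- key[u]
    hit <- cache[[k]]
    if (!is.null(hit)) return(hit)
    i <- idx[u]
    res <- reg$phenotypes[bits_from_mask(state$b_phres[i])]
    combos <- bits_from_mask(state$b_proph[i])
    proph <- if (length(combos))
      paste0(names(reg$phages)[combo_species(combos, reg)], ":",
             reg$phenotypes[combo_pheno(combos, reg)])
    else character()
    cache[[k]] <- make_genotype_label(
      names(reg$bacteria)[state$b_species[i]], state$b_abres[i], res, proph)
    cache[[k]]
  }, "")
  ulabs[match(key, key[uk])]
}

record_rows <- function(state, cache) {
  reg <- state$registry
  rows <- list()
  occ <- which(state$b_species != 0L)
  if (length(occ)) {
    lab <- genotype_labels_for(state, occ, cache)
    tab <- table(lab)
    rows[[length(rows) + 1L]] <-
      data.frame(entity_class = "bacterium", label = names(tab),
                 count = as.numeric(tab))
  }
  if (length(state$p_loc)) {
    lab <- paste0(names(reg$phages)[state$p_species], ":",
                  reg$phenotypes[state$p_pheno])
    tab <- table(lab)
    rows[[length(rows) + 1L]] <-
      data.frame(entity_class = "phage", label = names(tab),
                 count = as.numeric(tab))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    entity_class = "summary",
    label = c("total_bacteria", "total_free_virions", "total_antibiotic_mass"),
    count = c(length(occ), length(state$p_loc),
              total_antibiotic_mass(state$field)))
  rows[[length(rows) + 1L]] <- data.frame(
    entity_class = "event", label = names(state$tally),
    count = as.numeric(state$tally))
  out <- do.call(rbind, rows)
  out$iteration <- state$iter
  out[, c("iteration", "entity_class", "label", "count")]
}

new_trajectory <- function(rows, config, registry) {
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  class(traj) <- c("phage_trajectory", "data.frame")
  attr(traj, "meta") <- list(
    n_locations = n_locations(config),
    width = config$width, height = config$height,
    structure = config$structure,
    bacteria = names(registry$bacteria),
    phages = names(registry$phages),
    phenotypes = registry$phenotypes)
  traj
}

#' Initialize a simulation from configuration objects
#'
#' Builds the lattice, registry, antibiotic field and kill model from a
#' general-parameter list and an ecological setup (see [general_params()] and
#' [eco_setup()]), and places the inoculum: bacteria uniformly at random
#' without collision, free virions uniformly subject to the per-location cap.
#' Uses the current RNG stream; seed beforehand (or use [run_simulation()]).
#'
#' @param general A [general_params()] list.
#' @param eco An [eco_setup()] list.
#' @return A populated [simulation_state()].
#' @export
init_simulation <- function(general, eco) {
  config <- lattice_config(
    width = general$width, height = general$height,
    topology = general$topology, structure = general$structure,
    reproduction_radius = general$reproduction_radius,
    phage_diffusion_radius = general$phage_diffusion_radius,
    phage_cap_per_location = general$phage_cap_per_location)
  registry <- build_registry(eco)
  field <- antibiotic_field(
    config, degradation_rate = general$degradation_rate,
    diffusion_fraction = general$diffusion_fraction,
    deployment_mode = general$deployment_mode,
    n_foci = general$n_foci, dose = general$dose)
  kill <- kill_model(basal_death_prob = general$basal_death_prob,
                     antibiotic_kill_prob = general$antibiotic_kill_prob,
                     mic_threshold = general$mic_threshold)
  state <- simulation_state(config, registry, field, kill)
  total <- sum(vapply(eco$bacteria, function(b) as.integer(b$count), 0L))
  if (total > n_locations(config))
    stop("inoculum exceeds lattice size: ", total, " > ", n_locations(config))
  for (b in eco$bacteria)
    state <- place_bacteria(state, b$species$name, b$count,
                            prophages = b$prophages)
  for (p in eco$phages)
    if (p$count > 0L) state <- place_phages(state, p$species$name, p$count)
  state
}

#' Run a seeded simulation
#'
#' Seeds the RNG, initializes the state from the configuration pair, executes
#' `n_iterations` update cycles and returns the trajectory: per-iteration
#' counts of every bacterial genotype and free-phage attachment phenotype,
#' the population/virion/antibiotic totals, and the per-iteration event
#' tallies (births, deaths by cause, adsorptions, lyses, lysogenizations,
#' inductions, decays). A master seed fully determines the run.
#'
#' @param general A [general_params()] list.
#' @param eco An [eco_setup()] list.
#' @param seed Integer master seed.
#' @param validate Assert state invariants after every phase.
#' @param snapshot_every Write a lattice snapshot every this many iterations
#'   (`NULL` disables).
#' @param snapshot_file Path for snapshot output (tab-delimited; appended).
#' @return A `phage_trajectory` data frame with columns `iteration`,
#'   `entity_class`, `label`, `count` and one record block per iteration from
#'   0 to `n_iterations`.
#' @export
run_simulation <- function(general, eco, seed, validate = FALSE,
                           snapshot_every = general$snapshot_every,
                           snapshot_file = NULL) {
  set.seed(as.integer(seed))
  schedule <- schedule_config(
    n_iterations = general$n_iterations,
    antibiotic_application_iteration = general$antibiotic_application_iteration,
    repeat_doses_every = general$repeat_doses_every)
  state <- init_simulation(general, eco)
  if (validate) assert_state(state, "init")
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", schedule$n_iterations + 1L)
  rows[[1L]] <- record_rows(state, cache)
  snap <- function(s) {
    if (!is.null(snapshot_every) && !is.null(snapshot_file) &&
        s$iter %% snapshot_every == 0L)
      write_snapshot(s, snapshot_file, append = TRUE)
  }
  snap(state)
  for (it in seq_len(schedule$n_iterations)) {
    state$tally <- empty_tally()
    state <- simulation_step(state, schedule, validate = validate)
    rows[[it + 1L]] <- record_rows(state, cache)
    snap(state)
  }
  traj <- new_trajectory(rows, state$config, state$registry)
  attr(traj, "meta")$seed <- as.integer(seed)
  traj
}
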