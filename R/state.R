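# Simulation state: flat per-location vectors for bacteria (which makes the
# one-bacterium-per-location invariant structural) and parallel vectors for
# the free-virion pool.

#' Create an empty simulation state
#'
#' The state holds the lattice occupancy (one slot per location), the free
#' virion pool, the antibiotic field, the iteration counter and the event
#' tallies for the current iteration. Bacterial phenotypes are stored as flat
#' vectors indexed by location: species id (0 = empty), antibiotic-resistance
#' flag, resisted-phenotype bitmask, prophage bitmask and age. Use
#' [place_bacteria()] and [place_phages()] (or [init_simulation()]) to
#' populate it.
#'
#' @param config A [lattice_config()].
#' @param registry A [species_registry()].
#' @param field An [antibiotic_field()] (a zero field by default).
#' @param kill A [kill_model()].
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(config, registry, field = NULL, kill = NULL) {
  N <- n_locations(config)
  if (is.null(field)) field <- antibiotic_field(config)
  if (is.null(kill)) kill <- kill_model()
  radii <- sort(unique(c(1L, config$reproduction_radius,
                         config$phage_diffusion_radius)))
  radii <- radii[radii >= 1L]
  nbr <- lapply(radii, function(r) build_neighbor_index(config, r))
  names(nbr) <- as.character(radii)
  state <- list(
    config = config, registry = registry, field = field, kill = kill,
    b_species = integer(N), b_abres = logical(N), b_phres = integer(N),
    b_proph = integer(N), b_age = integer(N),
    lys_species = integer(N), lys_pheno = integer(N),
    p_loc = integer(0), p_species = integer(0), p_pheno = integer(0),
    p_age = integer(0), cap_overflow = 0L,
    iter = 0L, nbr = nbr, tally = empty_tally())
  class(state) <- "simulation_state"
  state
}

empty_tally <- function() {
  c(births = 0, deaths_basal = 0, deaths_antibiotic = 0, deaths_lysis = 0,
    adsorptions = 0, no_adsorption = 0, resistant_encounters = 0,
    aborted_superinfections = 0, lysogenizations = 0, inductions = 0,
    lyses = 0, burst_virions = 0, decays = 0, capacity_queued = 0,
    mutations_antibiotic = 0, mutations_phage = 0)
}

# total queued excess over the per-location cap (0 in ordinary regimes;
# positive only while a saturated neighborhood holds virions in queue)
compute_cap_overflow <- function(state) {
  if (!length(state$p_loc)) return(0L)
  cnt <- tabulate(state$p_loc, n_locations(state$config))
  as.integer(sum(pmax(cnt - state$config$phage_cap_per_location, 0L)))
}

state_nbr <- function(state, radius) {
  key <- as.character(radius)
  m <- state$nbr[[key]]
  if (is.null(m)) m <- build_neighbor_index(state$config, radius)
  m
}

#' Place bacteria of one species on the lattice
#'
#' Cells are placed uniformly at random on free locations (or at the given
#' locations), with the species' initial phenotype and optional initial
#' prophages.
#'
#' @param state A [simulation_state()].
#' @param species_name Name of a registry bacterial species.
#' @param count Number of cells to place.
#' @param locations Optional explicit location indices (1-based).
#' @param prophages Optional list of `list(species, attachment_phenotype)`
#'   records carried by every placed cell.
#' @return The updated state.
#' @export
place_bacteria <- function(state, species_name, count, locations = NULL,
                           prophages = list()) {
  reg <- state$registry
  sp <- bact_id(species_name, reg)
  count <- as.integer(count)
  if (count == 0L) return(state)
  free <- which(state$b_species == 0L)
  if (is.null(locations)) {
    if (count > length(free))
      stop("not enough free locations to place ", count, " bacteria")
    locations <- free[sample.int(length(free), count)]
  } else {
    locations <- as.integer(locations)
    if (any(state$b_species[locations] != 0L))
      stop("placement collision: location already occupied")
  }
  spec <- reg$bacteria[[sp]]
  state$b_species[locations] <- sp
  state$b_abres[locations] <- spec$antibiotic_resistant
  state$b_phres[locations] <-
    mask_from_bits(if (length(spec$phage_resistance_profile))
      pheno_id(spec$phage_resistance_profile, reg) else integer())
  proph_mask <- 0L
  for (p in prophages) {
    proph_mask <- set_bit(proph_mask,
                          combo_id(phage_id(p$species, reg),
                                   pheno_id(p$attachment_phenotype, reg), reg))
  }
  state$b_proph[locations] <- proph_mask
  state$b_age[locations] <- 0L
  state
}

#' Place free phage particles
#'
#' Particles are placed uniformly at random (or at the given locations),
#' subject to the per-location cap.
#'
#' @param state A [simulation_state()].
#' @param species_name Name of a registry phage species.
#' @param count Number of particles.
#' @param locations Optional explicit location indices.
#' @return The updated state.
#' @export
place_phages <- function(state, species_name, count, locations = NULL) {
  reg <- state$registry
  sp <- phage_id(species_name, reg)
  count <- as.integer(count)
  if (count == 0L) return(state)
  N <- n_locations(state$config)
  cap <- state$config$phage_cap_per_location
  if (length(state$p_loc) + count > N * cap)
    stop("free-virion pool exceeds lattice capacity")
  if (is.null(locations)) {
    locations <- sample.int(N, count, replace = TRUE)
  } else {
    locations <- rep_len(as.integer(locations), count)
  }
  ph <- pheno_id(reg$phages[[sp]]$attachment_phenotype, reg)
  state$p_loc <- c(state$p_loc, locations)
  state$p_species <- c(state$p_species, rep.int(sp, count))
  state$p_pheno <- c(state$p_pheno, rep.int(ph, count))
  state$p_age <- c(state$p_age, integer(count))
  # resolve any cap violations by uniform reassignment of the excess
  state <- enforce_phage_cap(state)
  state
}

# Reassign virions exceeding the per-location cap uniformly among
# under-capacity locations (used for initial placement and global mixing).
enforce_phage_cap <- function(state) {
  N <- n_locations(state$config)
  cap <- state$config$phage_cap_per_location
  repeat {
    cnt <- tabulate(state$p_loc, N)
    over <- which(cnt > cap)
    if (!length(over)) break
    sel <- which(state$p_loc %in% over)
    groups <- split(sel, state$p_loc[sel])
    excess <- unlist(lapply(groups, function(at)
      sample(at, length(at) - cap)), use.names = FALSE)
    under <- which(cnt < cap)
    if (!length(under)) {
      # whole lattice saturated: the excess stays queued where it is
      state$tally["capacity_queued"] <-
        state$tally["capacity_queued"] + length(excess)
      break
    }
    state$p_loc[excess] <- under[sample.int(length(under), length(excess),
                                            replace = TRUE)]
  }
  state$cap_overflow <- compute_cap_overflow(state)
  state
}

#' Randomize the lattice (well-mixed update)
#'
#' Emulates a liquid environment: bacteria are assigned a uniformly random
#' permutation over locations (at most one per location) and free virions are
#' uniformly redistributed subject to the per-location cap. The multisets of
#' agents are unchanged. Under any other structure mode this is the identity.
#'
#' @param state A [simulation_state()].
#' @return The mixed state.
#' @export
mix_well <- function(state) {
  if (state$config$structure != "well_mixed") return(state)
  N <- n_locations(state$config)
  occ <- which(state$b_species != 0L)
  n <- length(occ)
  if (n > N) stop("more bacteria than locations")
  if (n) {
    dest <- sample.int(N, n)
    for (f in c("b_species", "b_phres", "b_proph", "lys_species", "lys_pheno")) {
      v <- integer(N); v[dest] <- state[[f]][occ]; state[[f]] <- v
    }
    v <- logical(N); v[dest] <- state$b_abres[occ]; state$b_abres <- v
    v <- integer(N); v[dest] <- state$b_age[occ]; state$b_age <- v
  }
  if (length(state$p_loc)) {
    state$p_loc <- sample.int(N, length(state$p_loc), replace = TRUE)
    state <- enforce_phage_cap(state)
  }
  state
}

#' Diffuse free virions
#'
#' Each free virion moves to a uniformly chosen location within the
#' configured diffusion radius (staying put included). Proposals that would
#' exceed the per-location cap are retried among under-capacity locations in
#' the virion's neighborhood; when the whole neighborhood is saturated the
#' virion stays queued at its origin (counted in the `capacity_queued`
#' tally). The total virion count is unchanged.
#'
#' @param state A [simulation_state()].
#' @param subset Optional indices into the virion pool to move (used for
#'   post-burst local dispersal); all free virions by default.
#' @return The updated state.
#' @export
diffuse_phages <- function(state, subset = NULL) {
  r <- state$config$phage_diffusion_radius
  n_all <- length(state$p_loc)
  if (n_all == 0L) return(state)
  if (is.null(subset)) subset <- seq_len(n_all)
  if (!length(subset)) return(state)
  N <- n_locations(state$config)
  cap <- state$config$phage_cap_per_location

  origin <- state$p_loc[subset]
  if (r == 0L) {
    prop <- origin
  } else {
    nbr <- state_nbr(state, r)
    m <- ncol(nbr)
    prop <- integer(length(subset))
    todo <- seq_along(subset)
    # uniform over the valid candidate set (self + in-grid neighbors) by
    # rejection over the full (2r+1)^2 offset square
    while (length(todo)) {
      slot <- sample.int(m + 1L, length(todo), replace = TRUE)
      cand <- ifelse(slot > m, origin[todo],
                     nbr[cbind(origin[todo], pmin(slot, m))])
      ok <- cand <= N
      prop[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
  }

  cnt_fixed <- tabulate(state$p_loc[-subset], N)
  cnt <- cnt_fixed + tabulate(prop, N)
  over <- which(cnt > cap)
  if (length(over)) {
    sel <- which(prop %in% over)
    groups <- split(sel, prop[sel])
    retry <- unlist(lapply(groups, function(at) {
      room <- max(0L, cap - cnt_fixed[prop[at[1L]]])
      if (length(at) <= room) return(integer(0))
      if (room > 0L) at[-match(sample(at, room), at)] else at
    }), use.names = FALSE)
    cnt <- if (length(retry)) cnt_fixed + tabulate(prop[-retry], N) else cnt
    nbr1 <- if (r >= 1L) state_nbr(state, r) else NULL
    for (k in if (length(retry)) sample(retry) else integer(0)) {
      o <- origin[k]
      cand <- o
      if (!is.null(nbr1)) {
        nb <- nbr1[o, ]
        cand <- c(o, nb[nb <= N])
      }
      open <- cand[cnt[cand] < cap]
      if (length(open)) {
        tgt <- open[sample.int(length(open), 1L)]
        prop[k] <- tgt
        cnt[tgt] <- cnt[tgt] + 1L
      } else {
        prop[k] <- o  # queued at origin
        cnt[o] <- cnt[o] + 1L
        state$tally["capacity_queued"] <- state$tally["capacity_queued"] + 1
      }
    }
  }
  state$p_loc[subset] <- prop
  state$cap_overflow <- compute_cap_overflow(state)
  state
}

# Internal consistency assertions: occupancy/capacity invariants hold after
# every phase when the engine runs with validate = TRUE.
assert_state <- function(state, where = "") {
  N <- n_locations(state$config)
  stopifnot(length(state$b_species) == N)
  if (any(state$b_species < 0L))
    stop("internal consistency error (", where, "): negative species id")
  empty <- state$b_species == 0L
  if (any(state$b_phres[empty] != 0L) || any(state$b_proph[empty] != 0L) ||
      any(state$b_abres[empty]))
    stop("internal consistency error (", where, "): phantom phenotype at empty location")
  np <- length(state$p_loc)
  if (length(state$p_species) != np || length(state$p_pheno) != np ||
      length(state$p_age) != np)
    stop("internal consistency error (", where, "): ragged virion pool")
  if (np) {
    if (any(state$p_loc < 1L | state$p_loc > N))
      stop("internal consistency error (", where, "): virion off-lattice")
    if (compute_cap_overflow(state) > state$cap_overflow)
      stop("internal consistency error (", where, "): phage cap violated")
  }
  if (any(state$field$conc < 0))
    stop("internal consistency error (", where, "): negative antibiotic concentration")
  invisible(state)
}

# Population counts per bacterial species (by registry id).
species_counts <- function(state) {
  tabulate(state$b_species, length(state$registry$bacteria))
}
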