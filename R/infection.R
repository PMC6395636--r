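# Phage-host interaction logic: adsorption, superinfection exclusion, the
# lysis-lysogeny decision, bursts, prophage induction, virion decay and
# antibiotic killing.

#' Lysogenization probability at a given local phage density
#'
#' Evaluates the Hill response of a [lysogeny_curve()]:
#' `p_max * n^h / (n^h + K^h)`, with `n` the local free-phage count. Returns
#' 0 at `n = 0` and is monotone nondecreasing and bounded by `p_max`.
#'
#' @param local_phage_count Nonnegative integer (vectorized).
#' @param curve A [lysogeny_curve()].
#' @return Probability in `[0, p_max]`.
#' @export
lysogeny_probability <- function(local_phage_count, curve) {
  n <- as.numeric(local_phage_count)
  if (any(n < 0)) stop("local_phage_count must be >= 0")
  h <- curve$hill_exponent
  nh <- n^h
  out <- curve$p_max * nh / (nh + curve$half_density^h)
  out[n == 0] <- 0
  out
}

#' Antibiotic and basal mortality model
#'
#' @param basal_death_prob Default per-iteration probability of intrinsic
#'   death for species that do not set their own, in \[0,1\].
#' @param antibiotic_kill_prob Per-iteration death probability applied to
#'   antibiotic-sensitive cells whose local concentration is at or above
#'   `mic_threshold`.
#' @param mic_threshold Concentration (dose units) above which the antibiotic
#'   is lethal to sensitive cells (an MIC-like threshold, not a dose-response
#'   curve).
#' @return An object of class `kill_model`.
#' @export
kill_model <- function(basal_death_prob = 0.05, antibiotic_kill_prob = 0.95,
                       mic_threshold = 1) {
  if (basal_death_prob < 0 || basal_death_prob > 1)
    stop("basal_death_prob must be in [0,1]")
  if (antibiotic_kill_prob < 0 || antibiotic_kill_prob > 1)
    stop("antibiotic_kill_prob must be in [0,1]")
  if (mic_threshold < 0) stop("mic_threshold must be >= 0")
  structure(list(basal_death_prob = basal_death_prob,
                 antibiotic_kill_prob = antibiotic_kill_prob,
                 mic_threshold = mic_threshold),
            class = "kill_model")
}

#' One phage-host encounter
#'
#' Runs the sequential stochastic gates of a single encounter between a free
#' virion and a co-located host: (1) host resistance to the virion's
#' attachment phenotype; (2) adsorption, with probability
#' `host_range[phenotype, species] * adsorption_prob`; (3) superinfection
#' exclusion, checked independently against each resident prophage; (4) the
#' lifecycle decision - virulent phages always initiate lysis, temperate
#' phages lysogenize with probability
#' [lysogeny_probability()]`(local_phage_count)` and initiate lysis
#' otherwise. Defective phages adsorb but abort. An adsorbed virion is
#' consumed regardless of the step-3/4 outcome.
#'
#' @param virion A [phage_particle()].
#' @param host A [bacterium()].
#' @param registry The [species_registry()].
#' @param local_phage_count Free virions in the host's radius-1 Moore
#'   neighborhood (including its own location), used by the lysis-lysogeny
#'   decision.
#' @return A list with `kind` (one of `"resistant_host"`, `"no_adsorption"`,
#'   `"aborted_superinfection"`, `"lysis_initiated"`, `"lysogenized"`),
#'   `host` (updated when lysogenized) and `virion_consumed`.
#' @export
attempt_infection <- function(virion, host, registry, local_phage_count) {
  sp <- registry$phages[[virion$species]]
  if (is.null(sp)) stop("unknown phage species: ", virion$species)
  pheno <- virion$attachment_phenotype
  pheno_id(pheno, registry)                     # registry error if unknown
  hsp <- registry$bacteria[[host$species$name]]
  if (is.null(hsp)) stop("unknown bacterial species: ", host$species$name)

  if (pheno %in% host$resisted_phage_phenotypes)
    return(list(kind = "resistant_host", host = host, virion_consumed = FALSE))

  p_ads <- registry$host_range[pheno, host$species$name] * sp$adsorption_prob
  if (stats::runif(1) >= p_ads)
    return(list(kind = "no_adsorption", host = host, virion_consumed = FALSE))

  for (pr in host$prophages) {
    if (stats::runif(1) < registry$superinfection[virion$species, pr$species])
      return(list(kind = "aborted_superinfection", host = host,
                  virion_consumed = TRUE))
  }

  if (sp$lifestyle == "defective")
    return(list(kind = "aborted_superinfection", host = host,
                virion_consumed = TRUE))

  if (sp$lifestyle == "temperate" &&
      stats::runif(1) < lysogeny_probability(local_phage_count, sp$lysogeny_curve)) {
    host$prophages <- c(host$prophages,
                        list(list(species = sp$name,
                                  attachment_phenotype = pheno)))
    return(list(kind = "lysogenized", host = host, virion_consumed = TRUE))
  }
  list(kind = "lysis_initiated", host = host, virion_consumed = TRUE)
}

# state-level passes ----------------------------------------------------------

# Local free-phage counts (radius-1 Moore neighborhood including the focal
# location), a snapshot used by the lysis-lysogeny decisions of one pass.
local_phage_counts <- function(state) {
  N <- n_locations(state$config)
  cnt <- tabulate(state$p_loc, N)
  cnt + neighbor_sum(cnt, state_nbr(state, 1L))
}

# Probability that an incoming virion of each species escapes superinfection
# exclusion given a resident prophage mask: prod over resident prophage
# species of (1 - SI[incoming, resident]).
si_escape_prob <- function(proph_mask, incoming_sp, registry) {
  if (!length(proph_mask)) return(numeric(0))
  key <- proph_mask * (length(registry$phages) + 1) + incoming_sp
  uk <- !duplicated(key)
  uniq_mask <- proph_mask[uk]; uniq_sp <- incoming_sp[uk]
  q <- vapply(seq_along(uniq_mask), function(i) {
    combos <- bits_from_mask(uniq_mask[i])
    if (!length(combos)) return(1)
    res_sp <- unique(combo_species(combos, registry))
    prod(1 - registry$superinfection[uniq_sp[i], res_sp])
  }, 0)
  q[match(key, key[uk])]
}

# bitmask over phage species present in a prophage combo mask
proph_species_mask <- function(proph_mask, registry) {
  um <- unique(proph_mask)
  sp_mask <- vapply(um, function(m) {
    combos <- bits_from_mask(m)
    if (!length(combos)) return(0L)
    mask_from_bits(unique(combo_species(combos, registry)))
  }, 0L)
  sp_mask[match(proph_mask, um)]
}

# lysogenization probability per encounter, from the per-species Hill
# parameter vectors (NA / 0 for non-temperate species)
lys_prob_vec <- function(sp, n, registry) {
  pm <- registry$ps_lys_pmax[sp]
  k <- registry$ps_lys_k[sp]
  h <- registry$ps_lys_h[sp]
  nh <- n^h
  p <- pm * nh / (nh + k^h)
  p[is.na(p) | n == 0] <- 0
  p
}

#' Infection pass over the whole lattice
#'
#' Every free virion co-located with a bacterium attempts infection. Gates
#' that do not alter host state (resistance, adsorption) are evaluated for
#' all encounters at once; at locations where adsorbed temperate virions can
#' lysogenize (and thereby change the superinfection state seen by later
#' virions), encounters are resolved sequentially in random order. Adsorbed
#' virions are removed from the free pool; hosts with a lytic infection are
#' marked for lysis, resolved later in the iteration by [resolve_lyses()].
#' Local phage counts for the lysis-lysogeny decision are a snapshot taken at
#' the start of the pass.
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
infection_pass <- function(state) {
  if (!length(state$p_loc) || !any(state$b_species > 0L)) return(state)
  reg <- state$registry
  local_cnt <- local_phage_counts(state)

  v <- which(state$b_species[state$p_loc] > 0L)
  if (!length(v)) return(state)
  v <- if (length(v) > 1L) sample(v) else v   # global random encounter order

  loc <- state$p_loc[v]
  pheno <- state$p_pheno[v]
  vsp <- state$p_species[v]
  # gate 1: host resists the attachment phenotype
  resist <- bitwAnd(state$b_phres[loc], bitwShiftL(1L, pheno - 1L)) != 0L
  state$tally["resistant_encounters"] <-
    state$tally["resistant_encounters"] + sum(resist)
  # gate 2: adsorption
  hsp <- state$b_species[loc]
  p_ads <- reg$host_range[cbind(pheno, hsp)] * reg$ps_ads[vsp]
  ads <- !resist & stats::runif(length(v)) < p_ads
  state$tally["no_adsorption"] <-
    state$tally["no_adsorption"] + sum(!resist & !ads)
  if (!any(ads)) return(state)

  ai <- which(ads)
  state$tally["adsorptions"] <- state$tally["adsorptions"] + length(ai)
  a_loc <- loc[ai]; a_sp <- vsp[ai]; a_ph <- pheno[ai]
  life <- reg$ps_lifestyle[a_sp]
  temperate <- life == "temperate"

  # Superinfection exclusion depends only on the set of resident prophage
  # SPECIES, so encounters must be serialized only at locations where an
  # adsorbed temperate virion could add a new species mid-pass; everything
  # else is resolved in one vectorized sweep under the current (static)
  # prophage state.
  host_spmask <- proph_species_mask(state$b_proph[a_loc], reg)
  novel <- temperate & !has_bit(host_spmask, a_sp)
  seq_loc <- unique(a_loc[novel])
  fast <- !(a_loc %in% seq_loc)

  mark_lysis <- function(state, idx) {
    # first lytic outcome per location (in encounter order) claims the host
    if (!length(idx)) return(state)
    first <- idx[!duplicated(a_loc[idx])]
    newly <- first[state$lys_species[a_loc[first]] == 0L]
    state$lys_species[a_loc[newly]] <- a_sp[newly]
    state$lys_pheno[a_loc[newly]] <- a_ph[newly]
    state
  }

  if (any(fast)) {
    f <- which(fast)
    esc <- si_escape_prob(state$b_proph[a_loc[f]], a_sp[f], reg)
    abort <- stats::runif(length(f)) >= esc
    defect <- life[f] == "defective"
    open <- !abort & !defect
    lysog <- open & temperate[f] &
      stats::runif(length(f)) < lys_prob_vec(a_sp[f], local_cnt[a_loc[f]], reg)
    state$tally["aborted_superinfections"] <-
      state$tally["aborted_superinfections"] + sum(abort | (!abort & defect))
    if (any(lysog)) {
      li <- f[lysog]
      state$b_proph[a_loc[li]] <- bitwOr(
        state$b_proph[a_loc[li]],
        bitwShiftL(1L, combo_id(a_sp[li], a_ph[li], reg) - 1L))
      state$tally["lysogenizations"] <-
        state$tally["lysogenizations"] + length(li)
    }
    state <- mark_lysis(state, f[open & !lysog])
  }

  if (length(seq_loc)) {
    sel <- which(a_loc %in% seq_loc)
    groups <- split(sel, a_loc[sel])  # split preserves encounter order
    for (g in groups) {
      L <- a_loc[g[1L]]
      mask <- state$b_proph[L]
      idx <- g
      # rounds: commit outcomes until a lysogenization introduces a new
      # prophage species (which changes the exclusion probabilities for the
      # remaining virions), then redraw the remainder under the new state
      while (length(idx)) {
        spm <- proph_species_mask(mask, reg)
        esc <- si_escape_prob(rep.int(mask, length(idx)), a_sp[idx], reg)
        abort <- stats::runif(length(idx)) >= esc
        defect <- life[idx] == "defective"
        open <- !abort & !defect
        lysog <- open & temperate[idx] &
          stats::runif(length(idx)) <
            lys_prob_vec(a_sp[idx], local_cnt[L], reg)
        adds_species <- lysog & !has_bit(spm, a_sp[idx])
        cut <- if (any(adds_species)) which(adds_species)[1L]
        else length(idx)
        take <- seq_len(cut)
        state$tally["aborted_superinfections"] <-
          state$tally["aborted_superinfections"] +
          sum((abort | (!abort & defect))[take])
        tl <- idx[take][lysog[take]]
        if (length(tl)) {
          for (k in tl) mask <- set_bit(mask, combo_id(a_sp[k], a_ph[k], reg))
          state$tally["lysogenizations"] <-
            state$tally["lysogenizations"] + length(tl)
        }
        state <- mark_lysis(state, idx[take][open[take] & !lysog[take]])
        idx <- idx[-take]
      }
      state$b_proph[L] <- mask
    }
  }

  drop <- v[ai]
  state$p_loc <- state$p_loc[-drop]
  state$p_species <- state$p_species[-drop]
  state$p_pheno <- state$p_pheno[-drop]
  state$p_age <- state$p_age[-drop]
  if (state$cap_overflow > 0L)
    state$cap_overflow <- compute_cap_overflow(state)
  state
}

#' Prophage induction pass
#'
#' Each prophage of each living lysogen induces independently with
#' probability `min(1, induction_prob * stress_induction_factor)` when the
#' local antibiotic concentration is at or above the MIC threshold, and
#' `induction_prob` otherwise. An induced cell is scheduled for lysis in the
#' current iteration (releasing a burst of the induced prophage's species).
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
induce_prophages <- function(state) {
  lys <- which(state$b_proph != 0L & state$b_species != 0L)
  if (!length(lys)) return(state)
  reg <- state$registry
  stressed <- state$field$conc[lys] >= state$kill$mic_threshold
  n_combo <- length(reg$phages) * reg$n_pheno
  induced_any <- logical(length(lys))
  for (combo in seq_len(n_combo)) {
    carrier <- has_bit(state$b_proph[lys], combo)
    if (!any(carrier)) next
    sp <- combo_species(combo, reg)
    p <- pmin(1, reg$ps_induction[sp] *
                ifelse(stressed, reg$ps_stress[sp], 1))
    hit <- carrier & stats::runif(length(lys)) < p
    if (!any(hit)) next
    new_hit <- hit & !induced_any
    induced_any <- induced_any | hit
    tgt <- lys[new_hit]
    tgt <- tgt[state$lys_species[tgt] == 0L]
    if (length(tgt)) {
      state$lys_species[tgt] <- sp
      state$lys_pheno[tgt] <- combo_pheno(combo, reg)
    }
  }
  state$tally["inductions"] <- state$tally["inductions"] + sum(induced_any)
  state
}

#' Resolve all pending lyses
#'
#' Every cell marked for lysis (by a lytic infection or an induced prophage)
#' dies and frees its location; `burst_size` offspring virions of the
#' triggering species are created at the host location, each with an
#' attachment phenotype drawn through the per-offspring mutation rule, and
#' then disperse locally through the diffusion kernel (subject to the
#' per-location cap).
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
resolve_lyses <- function(state) {
  locs <- which(state$lys_species != 0L)
  if (!length(locs)) return(state)
  reg <- state$registry
  sp <- state$lys_species[locs]
  ph <- state$lys_pheno[locs]
  burst <- as.integer(reg$ps_burst[sp])

  # host death
  state$b_species[locs] <- 0L
  state$b_abres[locs] <- FALSE
  state$b_phres[locs] <- 0L
  state$b_proph[locs] <- 0L
  state$b_age[locs] <- 0L
  state$lys_species[locs] <- 0L
  state$lys_pheno[locs] <- 0L
  state$tally["lyses"] <- state$tally["lyses"] + length(locs)
  state$tally["deaths_lysis"] <- state$tally["deaths_lysis"] + length(locs)

  tot <- sum(burst)
  state$tally["burst_virions"] <- state$tally["burst_virions"] + tot
  if (tot == 0L) return(state)
  new_loc <- rep.int(locs, burst)
  new_sp <- rep.int(sp, burst)
  new_ph <- rep.int(ph, burst)
  # per-offspring attachment mutation, grouped by species
  for (s in unique(new_sp)) {
    i <- new_sp == s
    new_ph[i] <- mutate_phage_pheno_vec(new_ph[i], reg$ps_mu_att[s], reg$n_pheno)
  }
  n0 <- length(state$p_loc)
  state$p_loc <- c(state$p_loc, new_loc)
  state$p_species <- c(state$p_species, new_sp)
  state$p_pheno <- c(state$p_pheno, new_ph)
  state$p_age <- c(state$p_age, integer(tot))
  diffuse_phages(state, subset = n0 + seq_len(tot))
}

#' Resolve the lysis of one host
#'
#' Single-location form of [resolve_lyses()]; the location must carry a
#' pending lysis mark (set it directly or through [infection_pass()] /
#' [induce_prophages()]).
#'
#' @param state A [simulation_state()].
#' @param location Lattice index of the lysing host.
#' @return The updated state.
#' @export
resolve_lysis <- function(state, location) {
  if (state$lys_species[location] == 0L)
    stop("no pending lysis at location ", location)
  save_sp <- state$lys_species
  save_ph <- state$lys_pheno
  state$lys_species <- integer(length(save_sp))
  state$lys_pheno <- integer(length(save_ph))
  state$lys_species[location] <- save_sp[location]
  state$lys_pheno[location] <- save_ph[location]
  state <- resolve_lyses(state)
  save_sp[location] <- 0L
  save_ph[location] <- 0L
  state$lys_species <- save_sp
  state$lys_pheno <- save_ph
  state
}

#' Decay of free virions
#'
#' Each free virion ages by one iteration and is removed with its species'
#' per-iteration decay probability (a constant hazard; lifetimes are
#' geometric).
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
decay_free_phages <- function(state) {
  n <- length(state$p_loc)
  if (!n) return(state)
  state$p_age <- state$p_age + 1L
  gone <- stats::runif(n) < state$registry$ps_decay[state$p_species]
  if (any(gone)) {
    state$tally["decays"] <- state$tally["decays"] + sum(gone)
    keep <- !gone
    state$p_loc <- state$p_loc[keep]
    state$p_species <- state$p_species[keep]
    state$p_pheno <- state$p_pheno[keep]
    state$p_age <- state$p_age[keep]
    if (state$cap_overflow > 0L)
      state$cap_overflow <- compute_cap_overflow(state)
  }
  state
}

#' Basal and antibiotic mortality
#'
#' Each bacterium dies with its species' intrinsic death probability (the
#' kill model's basal probability when the species does not set one).
#' Additionally, antibiotic-sensitive cells at locations whose concentration
#' is at or above the MIC threshold die with `antibiotic_kill_prob`;
#' resistant cells ignore the antibiotic term. Dead cells free their
#' locations.
#'
#' @param state A [simulation_state()].
#' @return The updated state.
#' @export
apply_mortality <- function(state) {
  occ <- which(state$b_species != 0L)
  if (!length(occ)) return(state)
  reg <- state$registry
  basal <- reg$bs_death[state$b_species[occ]]
  basal[is.na(basal)] <- state$kill$basal_death_prob
  d1 <- stats::runif(length(occ)) < basal
  exposed <- !state$b_abres[occ] &
    state$field$conc[occ] >= state$kill$mic_threshold
  d2 <- exposed & stats::runif(length(occ)) < state$kill$antibiotic_kill_prob
  state$tally["deaths_basal"] <- state$tally["deaths_basal"] + sum(d1)
  state$tally["deaths_antibiotic"] <-
    state$tally["deaths_antibiotic"] + sum(d2 & !d1)
  dead <- occ[d1 | d2]
  if (length(dead)) {
    state$b_species[dead] <- 0L
    state$b_abres[dead] <- FALSE
    state$b_phres[dead] <- 0L
    state$b_proph[dead] <- 0L
    state$b_age[dead] <- 0L
  }
  state
}
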