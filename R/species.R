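# Species definitions, the interaction registry, fitness and mutation.
#
# Internally phage attachment-phenotype resistance is stored as a bitmask over
# the registry's phenotype list, and carried prophages as a bitmask over
# (phage species, attachment phenotype) combinations. Both masks must fit an
# R integer, which bounds the registry at 30 phenotype bits and 30
# species-phenotype combination bits; plenty for the community sizes this
# model targets.

valid_label <- function(x) {
  is.character(x) && length(x) == 1L && nzchar(x) &&
    !grepl("[+(),:[:space:]|]", x)
}

#' Define a bacterial species
#'
#' @param name Species label (no whitespace or the characters `+ ( ) , :`,
#'   which are reserved by genotype labels).
#' @param base_growth_rate Relative fitness of a cell with no resistance
#'   (>= 0).
#' @param intrinsic_death_prob Per-iteration probability of intrinsic death,
#'   in \[0,1\]. `NULL` means "use the global basal death probability of the
#'   kill model".
#' @param antibiotic_resistant Initial antibiotic-resistance phenotype.
#' @param phage_resistance_profile Character vector of phage attachment
#'   phenotypes the species initially resists.
#' @param cost_antibiotic_resistance Multiplicative fitness cost of antibiotic
#'   resistance, in \[0,1).
#' @param cost_phage_resistance Multiplicative fitness cost per resisted
#'   attachment phenotype, in \[0,1).
#' @param mu_antibiotic Probability that an offspring gains antibiotic
#'   resistance, applied once per reproduction event.
#' @param mu_phage_receptor Probability that an offspring gains resistance to
#'   one uniformly chosen attachment phenotype it does not already resist,
#'   applied once per reproduction event.
#' @return An object of class `bacterial_species`.
#' @export
bacterial_species <- function(name, base_growth_rate = 1,
                              intrinsic_death_prob = NULL,
                              antibiotic_resistant = FALSE,
                              phage_resistance_profile = character(),
                              cost_antibiotic_resistance = 0,
                              cost_phage_resistance = 0,
                              mu_antibiotic = 0,
                              mu_phage_receptor = 0) {
  if (!valid_label(name)) stop("invalid bacterial species name: ", name)
  if (base_growth_rate < 0) stop(name, ": base_growth_rate must be >= 0")
  probs <- c(mu_antibiotic = mu_antibiotic, mu_phage_receptor = mu_phage_receptor)
  if (!is.null(intrinsic_death_prob))
    probs <- c(probs, intrinsic_death_prob = intrinsic_death_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop(name, ": ", names(probs)[bad][1L], " must be in [0,1]")
  costs <- c(cost_antibiotic_resistance = cost_antibiotic_resistance,
             cost_phage_resistance = cost_phage_resistance)
  bad <- costs < 0 | costs >= 1
  if (any(bad)) stop(name, ": ", names(costs)[bad][1L], " must be in [0,1)")
  structure(
    list(name = name, base_growth_rate = base_growth_rate,
         intrinsic_death_prob = intrinsic_death_prob,
         antibiotic_resistant = isTRUE(antibiotic_resistant),
         phage_resistance_profile = as.character(phage_resistance_profile),
         cost_antibiotic_resistance = cost_antibiotic_resistance,
         cost_phage_resistance = cost_phage_resistance,
         mu_antibiotic = mu_antibiotic, mu_phage_receptor = mu_phage_receptor),
    class = "bacterial_species")
}

#' Define a phage species
#'
#' @param name Species label (same character restrictions as bacterial
#'   species).
#' @param lifestyle `"virulent"` (obligate lytic), `"temperate"` (lysis or
#'   lysogeny, governed by `lysogeny_curve`), or `"defective"` (adsorbs but
#'   causes no productive infection).
#' @param attachment_phenotype The phenotype free particles of this species
#'   carry at inoculation.
#' @param burst_size Virions released per lysis (integer >= 0).
#' @param adsorption_prob Per-encounter adsorption probability, multiplied by
#'   the host-range matrix entry.
#' @param decay_prob Per-iteration removal probability of a free virion (a
#'   constant hazard, i.e. geometric lifetime with half-life
#'   `log(2) / -log(1 - decay_prob)`).
#' @param mu_attachment Per-offspring probability that a burst virion carries
#'   a different, uniformly chosen attachment phenotype.
#' @param induction_prob Per-iteration spontaneous prophage induction
#'   probability.
#' @param stress_induction_factor Multiplier (>= 1) applied to
#'   `induction_prob` when the lysogen sits at or above the antibiotic MIC
#'   threshold.
#' @param lysogeny_curve A [lysogeny_curve()] (temperate species only).
#' @return An object of class `phage_species`.
#' @export
phage_species <- function(name,
                          lifestyle = c("virulent", "temperate", "defective"),
                          attachment_phenotype,
                          burst_size = 50L, adsorption_prob = 0.9,
                          decay_prob = 0.05, mu_attachment = 0,
                          induction_prob = 1e-3,
                          stress_induction_factor = 10,
                          lysogeny_curve = NULL) {
  lifestyle <- match.arg(lifestyle)
  if (!valid_label(name)) stop("invalid phage species name: ", name)
  if (!valid_label(attachment_phenotype))
    stop(name, ": invalid attachment_phenotype")
  burst_size <- as.integer(burst_size)
  if (is.na(burst_size) || burst_size < 0L)
    stop(name, ": burst_size must be an integer >= 0")
  probs <- c(adsorption_prob = adsorption_prob, decay_prob = decay_prob,
             mu_attachment = mu_attachment, induction_prob = induction_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop(name, ": ", names(probs)[bad][1L], " must be in [0,1]")
  if (stress_induction_factor < 1)
    stop(name, ": stress_induction_factor must be >= 1")
  if (lifestyle == "temperate") {
    if (is.null(lysogeny_curve))
      stop(name, ": temperate species require a lysogeny_curve")
    stopifnot(inherits(lysogeny_curve, "lysogeny_curve"))
  } else {
    lysogeny_curve <- NULL  # virulent/defective never lysogenize
  }
  if (lifestyle == "defective") burst_size <- 0L
  structure(
    list(name = name, lifestyle = lifestyle,
         attachment_phenotype = attachment_phenotype,
         burst_size = burst_size, adsorption_prob = adsorption_prob,
         decay_prob = decay_prob, mu_attachment = mu_attachment,
         induction_prob = induction_prob,
         stress_induction_factor = stress_induction_factor,
         lysogeny_curve = lysogeny_curve),
    class = "phage_species")
}

#' Density-dependent lysis-lysogeny response
#'
#' The probability that an adsorbing temperate phage lysogenizes its host is
#' a Hill function of the local free-phage count `n` (the virions in the
#' focal location's radius-1 Moore neighborhood, including the focal cell):
#' `p_max * n^h / (n^h + K^h)`, 0 at `n = 0`, monotone nondecreasing, bounded
#' by `p_max`.
#'
#' @param p_max Maximal lysogenization probability, in \[0,1\].
#' @param half_density Local phage count `K` at which the probability is
#'   `p_max / 2` (> 0).
#' @param hill_exponent Steepness `h` (>= 1).
#' @param preset_name Optional label; [lysogeny_preset()] supplies the three
#'   stock curves.
#' @return An object of class `lysogeny_curve`.
#' @export
lysogeny_curve <- function(p_max = 0.9, half_density = 15, hill_exponent = 2,
                           preset_name = "custom") {
  if (p_max < 0 || p_max > 1) stop("p_max must be in [0,1]")
  if (half_density <= 0) stop("half_density must be positive")
  if (hill_exponent < 1) stop("hill_exponent must be >= 1")
  structure(list(p_max = p_max, half_density = half_density,
                 hill_exponent = hill_exponent, preset_name = preset_name),
            class = "lysogeny_curve")
}

#' Stock lysogeny curves
#'
#' Three presets ordered by the phage density they require: `Lysogeny1`
#' (K = 5) and `Lysogeny2` (K = 15) reach appreciable lysogenization
#' probability at low local counts, while `Lysogeny3` (K = 150) requires very
#' high local density. All share `p_max = 0.9` and `h = 2`.
#'
#' @param name One of `"Lysogeny1"`, `"Lysogeny2"`, `"Lysogeny3"`.
#' @return A [lysogeny_curve()].
#' @export
lysogeny_preset <- function(name) {
  k <- switch(name, Lysogeny1 = 5, Lysogeny2 = 15, Lysogeny3 = 150,
              stop("unknown lysogeny preset: ", name))
  lysogeny_curve(p_max = 0.9, half_density = k, hill_exponent = 2,
                 preset_name = name)
}

#' Species registry: who infects whom
#'
#' Bundles the bacterial and phage species with the global list of attachment
#' phenotypes, the host-range matrix (rows = attachment phenotypes, columns =
#' bacterial species; entries are infection probabilities that multiply the
#' phage's adsorption probability) and the superinfection-exclusion matrix
#' (rows = incoming phage species, columns = resident prophage species;
#' entries are abort probabilities).
#'
#' @param bacteria List of [bacterial_species()] objects.
#' @param phages List of [phage_species()] objects.
#' @param phenotypes Character vector of all attachment phenotype labels.
#' @param host_range Numeric matrix `[phenotype, bacterial species]` in
#'   \[0,1\].
#' @param superinfection Numeric matrix `[incoming phage, resident prophage]`
#'   in \[0,1\]. Defaults to full exclusion within a species and none across.
#' @return An object of class `species_registry` carrying precomputed
#'   per-species parameter vectors used by the simulation engine.
#' @export
species_registry <- function(bacteria, phages, phenotypes,
                             host_range, superinfection = NULL) {
  stopifnot(length(bacteria) >= 1L)
  if (!all(vapply(bacteria, inherits, TRUE, "bacterial_species")))
    stop("bacteria must be a list of bacterial_species objects")
  if (length(phages) &&
      !all(vapply(phages, inherits, TRUE, "phage_species")))
    stop("phages must be a list of phage_species objects")
  bnames <- vapply(bacteria, `[[`, "", "name")
  pnames <- if (length(phages)) vapply(phages, `[[`, "", "name") else character()
  if (anyDuplicated(bnames)) stop("duplicate bacterial species names")
  if (anyDuplicated(pnames)) stop("duplicate phage species names")
  phenotypes <- as.character(phenotypes)
  if (!length(phenotypes) || anyDuplicated(phenotypes))
    stop("phenotypes must be a non-empty set of distinct labels")
  if (!all(vapply(phenotypes, valid_label, TRUE)))
    stop("invalid phenotype label")
  if (length(phenotypes) > 30L)
    stop("at most 30 attachment phenotypes are supported")
  if (length(pnames) * length(phenotypes) > 30L)
    stop("phage species x phenotype combinations exceed 30")

  host_range <- as.matrix(host_range)
  if (is.null(dimnames(host_range)))
    dimnames(host_range) <- list(phenotypes, bnames)
  if (!identical(rownames(host_range), phenotypes) ||
      !identical(colnames(host_range), bnames))
    stop("host_range must have rows = phenotypes, columns = bacterial species")
  bad <- which(host_range < 0 | host_range > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("host_range[", rownames(host_range)[bad[1, 1]], ", ",
         colnames(host_range)[bad[1, 2]], "] outside [0,1]")

  if (is.null(superinfection)) {
    superinfection <- diag(length(pnames))
    dimnames(superinfection) <- list(pnames, pnames)
  }
  superinfection <- as.matrix(superinfection)
  if (length(pnames)) {
    if (is.null(dimnames(superinfection)))
      dimnames(superinfection) <- list(pnames, pnames)
    if (!identical(rownames(superinfection), pnames) ||
        !identical(colnames(superinfection), pnames))
      stop("superinfection must be a phage x phage matrix")
    bad <- which(superinfection < 0 | superinfection > 1, arr.ind = TRUE)
    if (nrow(bad))
      stop("superinfection[", rownames(superinfection)[bad[1, 1]], ", ",
           colnames(superinfection)[bad[1, 2]], "] outside [0,1]")
  }

  for (b in bacteria) {
    missing <- setdiff(b$phage_resistance_profile, phenotypes)
    if (length(missing))
      stop(b$name, ": unknown phenotype in resistance profile: ", missing[1L])
  }
  for (p in phages) {
    if (!(p$attachment_phenotype %in% phenotypes))
      stop(p$name, ": unknown attachment_phenotype ", p$attachment_phenotype)
  }

  names(bacteria) <- bnames
  names(phages) <- pnames
  reg <- list(
    bacteria = bacteria, phages = phages, phenotypes = phenotypes,
    host_range = host_range, superinfection = superinfection,
    n_pheno = length(phenotypes),
    # flattened per-species parameter vectors (engine hot path)
    bs_growth = vapply(bacteria, `[[`, 0, "base_growth_rate"),
    bs_cost_ab = vapply(bacteria, `[[`, 0, "cost_antibiotic_resistance"),
    bs_cost_ph = vapply(bacteria, `[[`, 0, "cost_phage_resistance"),
    bs_death = vapply(bacteria, function(b)
      if (is.null(b$intrinsic_death_prob)) NA_real_ else b$intrinsic_death_prob, 0),
    bs_mu_ab = vapply(bacteria, `[[`, 0, "mu_antibiotic"),
    bs_mu_ph = vapply(bacteria, `[[`, 0, "mu_phage_receptor"),
    ps_lifestyle = vapply(phages, `[[`, "", "lifestyle"),
    ps_burst = vapply(phages, function(p) as.double(p$burst_size), 0),
    ps_ads = vapply(phages, `[[`, 0, "adsorption_prob"),
    ps_decay = vapply(phages, `[[`, 0, "decay_prob"),
    ps_mu_att = vapply(phages, `[[`, 0, "mu_attachment"),
    ps_induction = vapply(phages, `[[`, 0, "induction_prob"),
    ps_stress = vapply(phages, `[[`, 0, "stress_induction_factor"),
    ps_lys_pmax = vapply(phages, function(p)
      if (is.null(p$lysogeny_curve)) NA_real_ else p$lysogeny_curve$p_max, 0),
    ps_lys_k = vapply(phages, function(p)
      if (is.null(p$lysogeny_curve)) NA_real_
      else p$lysogeny_curve$half_density, 0),
    ps_lys_h = vapply(phages, function(p)
      if (is.null(p$lysogeny_curve)) NA_real_
      else p$lysogeny_curve$hill_exponent, 0))
  class(reg) <- "species_registry"
  reg
}

pheno_id <- function(label, registry) {
  i <- match(label, registry$phenotypes)
  if (anyNA(i)) stop("unknown attachment phenotype: ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

bact_id <- function(name, registry) {
  i <- match(name, names(registry$bacteria))
  if (anyNA(i)) stop("unknown bacterial species: ", name[is.na(i)][1L])
  i
}

phage_id <- function(name, registry) {
  i <- match(name, names(registry$phages))
  if (anyNA(i)) stop("unknown phage species: ", name[is.na(i)][1L])
  i
}

# bitmask helpers -----------------------------------------------------------

mask_from_bits <- function(bits) {
  if (!length(bits)) return(0L)
  sum(bitwShiftL(1L, unique(bits) - 1L))
}

bits_from_mask <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:29)) != 0L)

has_bit <- function(mask, bit) bitwAnd(mask, bitwShiftL(1L, bit - 1L)) != 0L

set_bit <- function(mask, bit) bitwOr(mask, bitwShiftL(1L, bit - 1L))

# vectorized population count for masks < 2^30
bit_count <- function(mask) {
  n <- integer(length(mask))
  for (b in 0:29) n <- n + bitwAnd(bitwShiftR(mask, b), 1L)
  n
}

# prophage combination encoding: (species s, phenotype p) -> (s-1)*n_pheno + p
combo_id <- function(sp, ph, registry) (sp - 1L) * registry$n_pheno + ph
combo_species <- function(combo, registry) (combo - 1L) %/% registry$n_pheno + 1L
combo_pheno <- function(combo, registry) (combo - 1L) %% registry$n_pheno + 1L

# agents ---------------------------------------------------------------------

#' A single bacterium
#'
#' A lightweight record used by the per-cell operations ([fitness()],
#' [roulette_select()], [mutate_offspring()], [attempt_infection()]); the
#' simulation engine stores the same state in flat per-location vectors.
#'
#' @param species A [bacterial_species()].
#' @param antibiotic_resistant Current antibiotic-resistance phenotype
#'   (defaults to the species' initial phenotype).
#' @param resisted_phage_phenotypes Attachment phenotypes the cell resists.
#' @param prophages List of prophage records, each
#'   `list(species = <phage name>, attachment_phenotype = <label>)`.
#' @param age Iterations lived.
#' @return An object of class `bacterium`.
#' @export
bacterium <- function(species, antibiotic_resistant = NULL,
                      resisted_phage_phenotypes = NULL,
                      prophages = list(), age = 0L) {
  stopifnot(inherits(species, "bacterial_species"))
  structure(
    list(species = species,
         antibiotic_resistant =
           if (is.null(antibiotic_resistant)) species$antibiotic_resistant
           else isTRUE(antibiotic_resistant),
         resisted_phage_phenotypes =
           if (is.null(resisted_phage_phenotypes))
             species$phage_resistance_profile
           else as.character(resisted_phage_phenotypes),
         prophages = prophages, age = as.integer(age)),
    class = "bacterium")
}

#' A free phage particle
#'
#' @param species A [phage_species()] or its name.
#' @param attachment_phenotype The particle's attachment phenotype (defaults
#'   to the species' initial phenotype when a species object is given).
#' @param age_outside_host Iterations since release.
#' @return An object of class `phage_particle`.
#' @export
phage_particle <- function(species, attachment_phenotype = NULL,
                           age_outside_host = 0L) {
  name <- if (inherits(species, "phage_species")) species$name else species
  if (is.null(attachment_phenotype)) {
    if (!inherits(species, "phage_species"))
      stop("attachment_phenotype required when species is given by name")
    attachment_phenotype <- species$attachment_phenotype
  }
  structure(list(species = name, attachment_phenotype = attachment_phenotype,
                 age_outside_host = as.integer(age_outside_host)),
            class = "phage_particle")
}

#' Bacterial fitness
#'
#' `base_growth_rate * (1 - cost_antibiotic_resistance)^[antibiotic resistant]
#'  * (1 - cost_phage_resistance)^(# resisted attachment phenotypes)`.
#' Costs compose multiplicatively, so fitness does not depend on the order in
#' which resistances were acquired and stays nonnegative.
#'
#' @param cell A [bacterium()].
#' @return Nonnegative fitness value.
#' @export
fitness <- function(cell) {
  sp <- cell$species
  f <- sp$base_growth_rate
  if (cell$antibiotic_resistant) f <- f * (1 - sp$cost_antibiotic_resistance)
  f * (1 - sp$cost_phage_resistance)^length(unique(cell$resisted_phage_phenotypes))
}

# index of the selected weight; uniform when all weights are zero
roulette_idx <- function(weights) {
  if (length(weights) == 1L) return(1L)
  total <- sum(weights)
  if (total <= 0) return(sample.int(length(weights), 1L))
  sample.int(length(weights), 1L, prob = weights)
}

#' Fitness-proportionate (roulette wheel) selection
#'
#' Selects one candidate with probability proportional to its [fitness()].
#' If every candidate has zero fitness the choice is uniform.
#'
#' @param candidates Nonempty list of [bacterium()] objects.
#' @return The selected bacterium.
#' @export
roulette_select <- function(candidates) {
  if (!length(candidates)) stop("candidates must be nonempty")
  w <- vapply(candidates, fitness, 0)
  candidates[[roulette_idx(w)]]
}

#' Create a (possibly mutated) offspring
#'
#' The offspring copies the parent's phenotype and prophages. Independently,
#' with probability `mu_antibiotic` it gains antibiotic resistance (if it
#' lacks it), and with probability `mu_phage_receptor` it gains resistance to
#' one uniformly chosen registry attachment phenotype it does not already
#' resist.
#'
#' @param parent A [bacterium()].
#' @param registry The [species_registry()].
#' @return The offspring bacterium (age 0).
#' @export
mutate_offspring <- function(parent, registry) {
  off <- parent
  off$age <- 0L
  sp <- parent$species
  if (!off$antibiotic_resistant && stats::runif(1) < sp$mu_antibiotic)
    off$antibiotic_resistant <- TRUE
  if (stats::runif(1) < sp$mu_phage_receptor) {
    avail <- setdiff(registry$phenotypes, off$resisted_phage_phenotypes)
    if (length(avail))
      off$resisted_phage_phenotypes <-
        c(off$resisted_phage_phenotypes, avail[sample.int(length(avail), 1L)])
  }
  off
}

#' Attachment-phenotype mutation of a burst virion
#'
#' With probability `mu_attachment` returns a uniformly chosen phenotype
#' different from the parent's; otherwise the parent phenotype. With fewer
#' than two phenotypes in the registry no mutation is possible.
#'
#' @param parent_phenotype Attachment phenotype of the lysing infection.
#' @param species The [phage_species()].
#' @param registry The [species_registry()].
#' @return An attachment phenotype label.
#' @export
mutate_phage_offspring <- function(parent_phenotype, species, registry) {
  pid <- pheno_id(parent_phenotype, registry)  # errors on unknown label
  n <- registry$n_pheno
  if (n < 2L || stats::runif(1) >= species$mu_attachment)
    return(parent_phenotype)
  shift <- sample.int(n - 1L, 1L)
  registry$phenotypes[(pid - 1L + shift) %% n + 1L]
}

# vectorized attachment mutation on phenotype ids (engine hot path)
mutate_phage_pheno_vec <- function(pheno, mu, n_pheno) {
  if (n_pheno < 2L || !length(pheno)) return(pheno)
  hit <- stats::runif(length(pheno)) < mu
  if (any(hit)) {
    shift <- sample.int(n_pheno - 1L, sum(hit), replace = TRUE)
    pheno[hit] <- (pheno[hit] - 1L + shift) %% n_pheno + 1L
  }
  pheno
}

# genotype labels ------------------------------------------------------------

#' Canonical genotype label
#'
#' A pure function of the phenotype: species name, then `+abR` if antibiotic
#' resistant, then `+r(...)` with the sorted resisted attachment phenotypes,
#' then `+lys(...)` with the sorted `species:phenotype` prophage records.
#'
#' @param cell A [bacterium()].
#' @return A single string.
#' @export
genotype_label <- function(cell) {
  make_genotype_label(
    cell$species$name, cell$antibiotic_resistant,
    cell$resisted_phage_phenotypes,
    vapply(cell$prophages, function(p)
      paste0(p$species, ":", p$attachment_phenotype), ""))
}

make_genotype_label <- function(species, abres, res_phenos, proph_labels) {
  out <- species
  if (abres) out <- paste0(out, "+abR")
  if (length(res_phenos))
    out <- paste0(out, "+r(", paste(sort(unique(res_phenos)), collapse = ","), ")")
  if (length(proph_labels))
    out <- paste0(out, "+lys(", paste(sort(unique(proph_labels)), collapse = ","), ")")
  out
}

#' Parse a genotype label
#'
#' Inverse of [genotype_label()]: reconstructs the phenotype fields encoded in
#' a canonical label.
#'
#' @param label A genotype label string.
#' @return A list with `species`, `antibiotic_resistant`,
#'   `resisted_phage_phenotypes` and `prophages` (list of
#'   `list(species, attachment_phenotype)`).
#' @export
parse_genotype_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  out <- list(species = parts[[1L]], antibiotic_resistant = FALSE,
              resisted_phage_phenotypes = character(), prophages = list())
  for (p in parts[-1L]) {
    if (p == "abR") {
      out$antibiotic_resistant <- TRUE
    } else if (startsWith(p, "r(")) {
      out$resisted_phage_phenotypes <-
        strsplit(substr(p, 3L, nchar(p) - 1L), ",", fixed = TRUE)[[1L]]
    } else if (startsWith(p, "lys(")) {
      recs <- strsplit(substr(p, 5L, nchar(p) - 1L), ",", fixed = TRUE)[[1L]]
      out$prophages <- lapply(recs, function(r) {
        kv <- strsplit(r, ":", fixed = TRUE)[[1L]]
        list(species = kv[[1L]], attachment_phenotype = kv[[2L]])
      })
    } else stop("malformed genotype label component: ", p)
  }
  out
}
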