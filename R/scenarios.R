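# Scenario presets: complete configuration pairs for the stock experiments,
# at 50 x 50 scale.

#' Scenario presets
#'
#' Returns a complete, validated `(general, eco)` configuration pair for one
#' of the stock experimental setups, with optional overrides applied last.
#'
#' Presets (all on a 50 x 50 bounded lattice):
#' \describe{
#'   \item{fig2_antibiotic}{two-species community - one phage-resistant but
#'     antibiotic-sensitive (`SphR`), one antibiotic-resistant but
#'     phage-sensitive (`SabR`), equal resistance costs - under a single
#'     slowly degrading antibiotic dose applied at iteration 10. No phage
#'     inoculum.}
#'   \item{fig2_phage}{the same community with 10 virulent phage particles
#'     co-inoculated at iteration 0 and no antibiotic.}
#'   \item{fig2_combined}{both stressors: phages at iteration 0, antibiotic
#'     at iteration 10.}
#'   \item{fig3_evolution}{a single species, initially sensitive to both
#'     stressors, that can mutate to antibiotic resistance and to phage
#'     resistance at rate 1e-4 per reproduction event each; both stressors
#'     applied.}
#'   \item{fig4_coevolution}{a single sensitive species (receptor-resistance
#'     mutations at 1e-3) against a virulent phage whose attachment
#'     phenotype mutates at 1e-4 between two phenotypes, enabling an arms
#'     race. Antibiotic resistance mutations at 1e-3 become relevant when an
#'     antibiotic schedule is switched on via overrides.}
#'   \item{fig5_invasion}{an invading lysogen population co-inoculated at a
#'     1:10 ratio with a phage-sensitive resident; the temperate prophage
#'     induces spontaneously, and the response of interest is the number of
#'     lysogenized residents at iteration 15. Well-mixed.}
#'   \item{fig6_invasion_structured}{the same invasion in a fully structured
#'     environment.}
#' }
#'
#' Overrides are named by dotted paths into the configuration pair, e.g.
#' `"general.structure"`, `"eco.phage.P.burst_size"`,
#' `"eco.bacterium.S.mu_phage_receptor"`, `"eco.phage.P.lysogeny_curve"`
#' (a preset name). When `general.structure` is overridden to `"structured"`
#' and no explicit radius override is given, `phage_diffusion_radius` is set
#' to 1 (limited diffusion is what structure means for virions).
#'
#' @param name Preset label.
#' @param overrides Named list of dotted-path overrides.
#' @return A list with `general` and `eco`.
#' @export
scenario <- function(name, overrides = list()) {
  builder <- switch(name,
                    fig2_antibiotic = ,
                    fig2_phage = ,
                    fig2_combined = scenario_fig2,
                    fig3_evolution = scenario_fig3,
                    fig4_coevolution = scenario_fig4,
                    fig5_invasion = scenario_fig5,
                    fig6_invasion_structured = scenario_fig6,
                    stop("unknown scenario preset: ", name))
  pair <- builder(name)
  apply_overrides(pair, overrides)
}

apply_overrides <- function(pair, overrides) {
  if (!length(overrides)) return(revalidate_pair(pair))
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("overrides must be a named list")
  structure_override <- "general.structure" %in% names(overrides)
  radius_override <- "general.phage_diffusion_radius" %in% names(overrides)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    val <- overrides[[key]]
    if (parts[[1L]] == "general") {
      if (length(parts) != 2L) stop("malformed override key: ", key)
      pair$general[[parts[[2L]]]] <- val
    } else if (parts[[1L]] == "eco") {
      if (length(parts) == 2L) {
        pair$eco[[parts[[2L]]]] <- val
      } else if (length(parts) == 4L && parts[[2L]] %in% c("bacterium", "phage")) {
        slot <- if (parts[[2L]] == "bacterium") "bacteria" else "phages"
        found <- FALSE
        for (i in seq_along(pair$eco[[slot]])) {
          if (pair$eco[[slot]][[i]]$species$name == parts[[3L]]) {
            found <- TRUE
            field <- parts[[4L]]
            if (field == "count") {
              pair$eco[[slot]][[i]]$count <- val
            } else if (field == "lysogeny_curve" && is.character(val)) {
              pair$eco[[slot]][[i]]$species$lysogeny_curve <-
                lysogeny_preset(val)
            } else {
              pair$eco[[slot]][[i]]$species[[field]] <- val
            }
          }
        }
        if (!found) stop("override targets unknown species: ", key)
      } else stop("malformed override key: ", key)
    } else stop("malformed override key: ", key)
  }
  if (structure_override && !radius_override &&
      identical(overrides[["general.structure"]], "structured"))
    pair$general$phage_diffusion_radius <- 1L
  revalidate_pair(pair)
}

revalidate_pair <- function(pair) {
  g <- unclass(pair$general)
  pair$general <- do.call(general_params, g[!vapply(g, is.null, TRUE)])
  e <- pair$eco
  pair$eco <- eco_setup(bacteria = e$bacteria, phages = e$phages,
                        phenotypes = e$phenotypes,
                        host_range = e$host_range,
                        superinfection = e$superinfection)
  pair
}

scenario_fig2 <- function(variant) {
  general <- general_params(
    structure = "well_mixed", n_iterations = 80L,
    antibiotic_application_iteration =
      if (variant %in% c("fig2_antibiotic", "fig2_combined")) 10L else NULL,
    deployment_mode = "homogeneous")
  phage_count <- if (variant %in% c("fig2_phage", "fig2_combined")) 10L else 0L
  eco <- eco_setup(
    bacteria = list(
      list(species = bacterial_species(
        "SphR", phage_resistance_profile = "a",
        cost_phage_resistance = 0.1), count = 1100L),
      list(species = bacterial_species(
        "SabR", antibiotic_resistant = TRUE,
        cost_antibiotic_resistance = 0.1), count = 1100L)),
    phages = list(
      list(species = phage_species("P", "virulent",
                                   attachment_phenotype = "a"),
           count = phage_count)),
    phenotypes = "a",
    host_range = matrix(c(0.9, 0.9), 1, 2,
                        dimnames = list("a", c("SphR", "SabR"))))
  list(general = general, eco = eco)
}

scenario_fig3 <- function(variant) {
  general <- general_params(
    structure = "well_mixed", n_iterations = 80L,
    antibiotic_application_iteration = 10L,
    deployment_mode = "homogeneous")
  eco <- eco_setup(
    bacteria = list(
      list(species = bacterial_species(
        "S", cost_antibiotic_resistance = 0.1, cost_phage_resistance = 0.1,
        mu_antibiotic = 1e-4, mu_phage_receptor = 1e-4), count = 2200L)),
    phages = list(
      list(species = phage_species("P", "virulent",
                                   attachment_phenotype = "a"),
           count = 10L)),
    phenotypes = "a",
    host_range = matrix(0.9, 1, 1, dimnames = list("a", "S")))
  list(general = general, eco = eco)
}

scenario_fig4 <- function(variant) {
  general <- general_params(
    structure = "well_mixed", n_iterations = 80L,
    deployment_mode = "heterogeneous")
  eco <- eco_setup(
    bacteria = list(
      list(species = bacterial_species(
        "S", cost_antibiotic_resistance = 0.1, cost_phage_resistance = 0.05,
        mu_antibiotic = 1e-3, mu_phage_receptor = 1e-3), count = 2200L)),
    phages = list(
      list(species = phage_species("P", "virulent",
                                   attachment_phenotype = "a",
                                   mu_attachment = 1e-4),
           count = 10L)),
    phenotypes = c("a", "b"),
    host_range = matrix(c(0.9, 0.9), 2, 1,
                        dimnames = list(c("a", "b"), "S")))
  list(general = general, eco = eco)
}

scenario_fig5 <- function(variant, structure = "well_mixed") {
  general <- general_params(structure = structure, n_iterations = 30L)
  if (structure == "structured") general$phage_diffusion_radius <- 1L
  eco <- eco_setup(
    bacteria = list(
      list(species = bacterial_species("S"), count = 2000L),
      list(species = bacterial_species("L"), count = 200L,
           prophages = list(list(species = "P", attachment_phenotype = "a")))),
    phages = list(
      list(species = phage_species(
        "P", "temperate", attachment_phenotype = "a",
        induction_prob = 0.01,
        lysogeny_curve = lysogeny_preset("Lysogeny2")), count = 0L)),
    phenotypes = "a",
    host_range = matrix(c(0.9, 0.9), 1, 2,
                        dimnames = list("a", c("S", "L"))),
    superinfection = matrix(1, 1, 1, dimnames = list("P", "P")))
  list(general = general, eco = eco)
}

scenario_fig6 <- function(variant) scenario_fig5(variant, structure = "structured")

# trajectory accessors ---------------------------------------------------------

#' Per-iteration counts for one label
#'
#' Extracts the time series of a label from a trajectory, filling iterations
#' where the label was not recorded with zero.
#'
#' @param trajectory A `phage_trajectory`.
#' @param label The genotype / phage / summary / event label.
#' @param entity_class Restrict to one entity class (recommended; label
#'   namespaces can overlap).
#' @return A numeric vector indexed by iteration 0..n (named by iteration).
#' @export
traj_counts <- function(trajectory, label, entity_class = NULL) {
  iters <- 0:max(trajectory$iteration)
  sel <- trajectory$label == label
  if (!is.null(entity_class)) sel <- sel & trajectory$entity_class == entity_class
  out <- numeric(length(iters))
  names(out) <- iters
  hit <- trajectory[sel, , drop = FALSE]
  out[as.character(hit$iteration)] <- hit$count
  out
}

#' Labels ever recorded in one entity class of a trajectory
#'
#' @param trajectory A `phage_trajectory`.
#' @param entity_class One of `"bacterium"`, `"phage"`, `"summary"`,
#'   `"event"`.
#' @return Character vector of distinct labels.
#' @export
traj_labels <- function(trajectory, entity_class) {
  unique(trajectory$label[trajectory$entity_class == entity_class])
}

#' Per-iteration count of a bacterial species across all its genotypes
#'
#' Sums every genotype label belonging to the species (a species can split
#' into many genotypes as resistances and prophages accumulate).
#'
#' @param trajectory A `phage_trajectory`.
#' @param species Bacterial species name.
#' @return A numeric vector indexed by iteration 0..n.
#' @export
traj_species_counts <- function(trajectory, species) {
  labels <- traj_labels(trajectory, "bacterium")
  mine <- labels[vapply(labels, function(l)
    parse_genotype_label(l)$species == species, TRUE)]
  n_it <- max(trajectory$iteration) + 1L
  if (!length(mine)) {
    out <- numeric(n_it)
    names(out) <- 0:(n_it - 1L)
    return(out)
  }
  rowSums(vapply(mine, function(l)
    traj_counts(trajectory, l, "bacterium"), numeric(n_it)))
}

#' First iteration at which a bacterial species disappears
#'
#' @param trajectory A `phage_trajectory`.
#' @param species Bacterial species name.
#' @return Integer iteration or `NA` if the species survives to the end (or
#'   was never present).
#' @export
species_extinction_iteration <- function(trajectory, species) {
  x <- traj_species_counts(trajectory, species)
  seen <- which(x > 0)
  if (!length(seen)) return(NA_integer_)
  gone <- which(x == 0 & seq_along(x) > seen[1L])
  if (!length(gone)) return(NA_integer_)
  as.integer(names(x)[gone[1L]])
}

#' First iteration at which a population hits zero
#'
#' @param trajectory A `phage_trajectory`.
#' @param label Genotype or phage label.
#' @param entity_class Entity class of the label.
#' @return The first iteration with count 0 after the label was present, or
#'   `NA` if the population never goes extinct (or was never present).
#' @export
extinction_iteration <- function(trajectory, label, entity_class = "bacterium") {
  x <- traj_counts(trajectory, label, entity_class)
  seen <- which(x > 0)
  if (!length(seen)) return(NA_integer_)
  gone <- which(x == 0 & seq_along(x) > seen[1L])
  if (!length(gone)) return(NA_integer_)
  as.integer(names(x)[gone[1L]])
}
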