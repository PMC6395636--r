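# Shared fixtures: small registries, states and configuration pairs built in
# code at test time.

tiny_config <- function(...) {
  lattice_config(width = 10L, height = 10L, ...)
}

# two bacterial species, one virulent phage on phenotype "a"
tiny_registry <- function(mu_ab = 0, mu_ph = 0, burst = 10L,
                          adsorption = 1, decay = 0,
                          lifestyle = "virulent", curve = NULL,
                          mu_att = 0, induction = 0, stress = 1,
                          phenotypes = c("a", "b")) {
  species_registry(
    bacteria = list(
      bacterial_species("S1", mu_antibiotic = mu_ab, mu_phage_receptor = mu_ph,
                        cost_antibiotic_resistance = 0.1,
                        cost_phage_resistance = 0.05),
      bacterial_species("S2", antibiotic_resistant = TRUE,
                        cost_antibiotic_resistance = 0.1)),
    phages = list(
      phage_species("P", lifestyle, attachment_phenotype = "a",
                    burst_size = burst, adsorption_prob = adsorption,
                    decay_prob = decay, mu_attachment = mu_att,
                    induction_prob = induction,
                    stress_induction_factor = stress,
                    lysogeny_curve = curve)),
    phenotypes = phenotypes,
    host_range = matrix(1, length(phenotypes), 2,
                        dimnames = list(phenotypes, c("S1", "S2"))),
    superinfection = matrix(1, 1, 1, dimnames = list("P", "P")))
}

tiny_state <- function(config = tiny_config(), registry = tiny_registry(),
                       kill = kill_model(basal_death_prob = 0,
                                         antibiotic_kill_prob = 0,
                                         mic_threshold = 1)) {
  simulation_state(config, registry, kill = kill)
}

# minimal valid config pair for engine tests (no phage activity by default)
tiny_pair <- function(n_bact = 40L, n_phage = 0L, n_iterations = 5L,
                      basal_death_prob = 0.05, ...) {
  general <- general_params(width = 10L, height = 10L,
                            basal_death_prob = basal_death_prob,
                            n_iterations = n_iterations, ...)
  eco <- eco_setup(
    bacteria = list(
      list(species = bacterial_species("S1"), count = n_bact %/% 2L),
      list(species = bacterial_species("S2"), count = n_bact - n_bact %/% 2L)),
    phages = list(
      list(species = phage_species("P", "virulent",
                                   attachment_phenotype = "a",
                                   burst_size = 10L, decay_prob = 0.05),
           count = n_phage)),
    phenotypes = "a",
    host_range = matrix(c(0.9, 0.9), 1, 2,
                        dimnames = list("a", c("S1", "S2"))))
  list(general = general, eco = eco)
}

# brute-force Moore neighborhood by coordinate enumeration (test oracle)
brute_neighborhood <- function(x, y, radius, config) {
  out <- NULL
  for (dx in -radius:radius) for (dy in -radius:radius) {
    if (dx == 0 && dy == 0) next
    nx <- x + dx; ny <- y + dy
    if (config$topology == "toroidal") {
      nx <- nx %% config$width; ny <- ny %% config$height
    } else if (nx < 0 || nx >= config$width || ny < 0 || ny >= config$height) {
      next
    }
    out <- rbind(out, c(nx, ny))
  }
  unique(out)
}

# Yates-corrected 2x2 chi-squared by direct formula (test oracle)
yates_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)^2 * n
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  num / den
}
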