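# Configuration objects, the two plain-text input files, and the delimited
# trajectory / snapshot writers.
#
# A run is specified by two text files: a general-parameter file (flat
# `key = value` lines) and an ecological-setup file (INI-style sections for
# phenotypes, each species, and whitespace-delimited matrix blocks). The
# grammar is this package's own; see the package vignette for a worked
# example.

general_param_defaults <- function() {
  list(width = 50L, height = 50L, topology = "bounded",
       structure = "well_mixed", reproduction_radius = 3L,
       phage_diffusion_radius = 3L, phage_cap_per_location = 50L,
       degradation_rate = 0.01, diffusion_fraction = 0.2,
       deployment_mode = "homogeneous", n_foci = 10L, dose = 10,
       basal_death_prob = 0.05, antibiotic_kill_prob = 0.95,
       mic_threshold = 1, n_iterations = 80L,
       antibiotic_application_iteration = NULL, repeat_doses_every = NULL,
       snapshot_every = NULL, seed = NULL)
}

#' General simulation parameters
#'
#' All lattice, antibiotic, mortality and schedule scalars in one validated
#' list. Any field not supplied takes its documented default.
#'
#' @param ... Named fields; see [lattice_config()], [antibiotic_field()],
#'   [kill_model()] and [schedule_config()] for their meaning. Additional
#'   global toggles: `snapshot_every` (lattice snapshot cadence) and `seed`.
#' @return A validated list of class `general_params`.
#' @export
general_params <- function(...) {
  defaults <- general_param_defaults()
  supplied <- list(...)
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown))
    stop("unknown general parameter(s): ", paste(unknown, collapse = ", "))
  g <- utils::modifyList(defaults, supplied, keep.null = TRUE)
  # constructor round trips double as validation naming the offending field
  cfg <- lattice_config(g$width, g$height, g$topology, g$structure,
                        g$reproduction_radius, g$phage_diffusion_radius,
                        g$phage_cap_per_location)
  g$width <- cfg$width; g$height <- cfg$height
  g$reproduction_radius <- cfg$reproduction_radius
  antibiotic_field(cfg, g$degradation_rate, g$diffusion_fraction,
                   g$deployment_mode, g$n_foci, g$dose)
  kill_model(g$basal_death_prob, g$antibiotic_kill_prob, g$mic_threshold)
  schedule_config(g$n_iterations, g$antibiotic_application_iteration,
                  g$repeat_doses_every)
  if (!is.null(g$snapshot_every) && g$snapshot_every < 1)
    stop("snapshot_every must be >= 1")
  g$n_iterations <- as.integer(g$n_iterations)
  g$n_foci <- as.integer(g$n_foci)
  structure(g, class = "general_params")
}

#' Ecological setup
#'
#' The species present at inoculation, their initial counts and attributes,
#' and the interaction matrices.
#'
#' @param bacteria List of entries `list(species = bacterial_species(),
#'   count = <int>, prophages = <optional list of
#'   list(species, attachment_phenotype)>)`.
#' @param phages List of entries `list(species = phage_species(),
#'   count = <int>)` giving the initial free particles per species.
#' @param phenotypes Character vector of all attachment phenotype labels.
#' @param host_range,superinfection See [species_registry()].
#' @return A validated list of class `eco_setup`.
#' @export
eco_setup <- function(bacteria, phages = list(), phenotypes,
                      host_range, superinfection = NULL) {
  bacteria <- lapply(bacteria, function(b) {
    stopifnot(inherits(b$species, "bacterial_species"))
    b$count <- as.integer(b$count)
    if (is.na(b$count) || b$count < 0L)
      stop(b$species$name, ": count must be a nonnegative integer")
    if (is.null(b$prophages)) b$prophages <- list()
    b
  })
  phages <- lapply(phages, function(p) {
    stopifnot(inherits(p$species, "phage_species"))
    p$count <- as.integer(p$count)
    if (is.na(p$count) || p$count < 0L)
      stop(p$species$name, ": count must be a nonnegative integer")
    p
  })
  eco <- structure(
    list(bacteria = bacteria, phages = phages,
         phenotypes = as.character(phenotypes),
         host_range = host_range, superinfection = superinfection),
    class = "eco_setup")
  build_registry(eco)   # full referential/range validation
  eco
}

build_registry <- function(eco) {
  reg <- species_registry(
    bacteria = lapply(eco$bacteria, `[[`, "species"),
    phages = lapply(eco$phages, `[[`, "species"),
    phenotypes = eco$phenotypes,
    host_range = eco$host_range,
    superinfection = eco$superinfection)
  for (b in eco$bacteria) {
    for (p in b$prophages) {
      phage_id(p$species, reg)
      pheno_id(p$attachment_phenotype, reg)
    }
  }
  reg
}

# text-file parsing ------------------------------------------------------------

strip_comment <- function(x) sub("#.*$", "", x)

parse_scalar <- function(value, field) {
  v <- trimws(value)
  if (v %in% c("none", "null", "NULL")) return(NULL)
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

read_kv_block <- function(lines, context) {
  out <- list()
  for (ln in lines) {
    ln <- trimws(strip_comment(ln))
    if (!nzchar(ln)) next
    if (!grepl("=", ln, fixed = TRUE))
      stop(context, ": malformed line (expected key = value): ", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[[1L]])
    out[[key]] <- parse_scalar(paste(kv[-1L], collapse = "="), key)
  }
  out
}

#' Parse the two simulation input files
#'
#' Reads and validates a general-parameter file (flat `key = value`) and an
#' ecological-setup file (INI-style sections: `[phenotypes]`,
#' `[bacterium <name>]`, `[phage <name>]`, `[host_range]`,
#' `[superinfection]`). Unknown keys are errors, and every default filled in
#' is echoed as a message.
#'
#' @param general_path,eco_path File paths.
#' @return A list with elements `general` ([general_params()]) and `eco`
#'   ([eco_setup()]).
#' @export
parse_configs <- function(general_path, eco_path) {
  for (p in c(general_path, eco_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  kv <- read_kv_block(readLines(general_path), basename(general_path))
  defaults <- general_param_defaults()
  unknown <- setdiff(names(kv), names(defaults))
  if (length(unknown))
    stop(basename(general_path), ": unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(names(defaults), names(kv))
  if (length(missing))
    message("general parameters using defaults: ",
            paste(missing, collapse = ", "))
  general <- do.call(general_params, kv)
  eco <- parse_eco_file(eco_path)
  list(general = general, eco = eco)
}

bact_field_names <- c("count", "base_growth_rate", "intrinsic_death_prob",
                      "antibiotic_resistant", "phage_resistance_profile",
                      "cost_antibiotic_resistance", "cost_phage_resistance",
                      "mu_antibiotic", "mu_phage_receptor", "prophages")
phage_field_names <- c("count", "lifestyle", "attachment_phenotype",
                       "burst_size", "adsorption_prob", "decay_prob",
                       "mu_attachment", "induction_prob",
                       "stress_induction_factor", "lysogeny_curve")

parse_eco_file <- function(path) {
  lines <- readLines(path)
  headers <- grep("^\\s*\\[.*\\]\\s*$", lines)
  if (!length(headers)) stop(basename(path), ": no sections found")
  bounds <- c(headers, length(lines) + 1L)
  sections <- lapply(seq_along(headers), function(i) {
    list(name = trimws(gsub("\\[|\\]", "", lines[headers[i]])),
         lines = lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)][
           seq_len(max(0L, bounds[i + 1L] - headers[i] - 1L))])
  })
  phenotypes <- character()
  bacteria <- list(); phages <- list()
  host_range <- NULL; superinfection <- NULL
  for (sec in sections) {
    words <- strsplit(trimws(sec$name), "\\s+")[[1L]]
    kind <- words[[1L]]
    if (kind == "phenotypes") {
      txt <- trimws(strip_comment(paste(sec$lines, collapse = " ")))
      phenotypes <- strsplit(txt, "\\s+")[[1L]]
      phenotypes <- phenotypes[nzchar(phenotypes)]
    } else if (kind == "bacterium") {
      if (length(words) < 2L) stop(basename(path), ": bacterium section needs a name")
      kv <- read_kv_block(sec$lines, paste("bacterium", words[[2L]]))
      unknown <- setdiff(names(kv), bact_field_names)
      if (length(unknown))
        stop("bacterium ", words[[2L]], ": unknown field(s): ",
             paste(unknown, collapse = ", "))
      prof <- if (is.null(kv$phage_resistance_profile)) character()
      else strsplit(trimws(kv$phage_resistance_profile), "\\s+")[[1L]]
      proph <- list()
      if (!is.null(kv$prophages)) {
        for (rec in strsplit(trimws(kv$prophages), "\\s+")[[1L]]) {
          pr <- strsplit(rec, ":", fixed = TRUE)[[1L]]
          if (length(pr) != 2L)
            stop("bacterium ", words[[2L]],
                 ": prophage records must be species:phenotype")
          proph[[length(proph) + 1L]] <-
            list(species = pr[[1L]], attachment_phenotype = pr[[2L]])
        }
      }
      spec_args <- kv[setdiff(names(kv),
                              c("count", "phage_resistance_profile", "prophages"))]
      sp <- do.call(bacterial_species,
                    c(list(name = words[[2L]],
                           phage_resistance_profile = prof), spec_args))
      bacteria[[length(bacteria) + 1L]] <-
        list(species = sp, count = if (is.null(kv$count)) 0L else kv$count,
             prophages = proph)
    } else if (kind == "phage") {
      if (length(words) < 2L) stop(basename(path), ": phage section needs a name")
      kv <- read_kv_block(sec$lines, paste("phage", words[[2L]]))
      unknown <- setdiff(names(kv), phage_field_names)
      if (length(unknown))
        stop("phage ", words[[2L]], ": unknown field(s): ",
             paste(unknown, collapse = ", "))
      curve <- NULL
      if (!is.null(kv$lysogeny_curve)) {
        cv <- kv$lysogeny_curve
        if (is.character(cv)) {
          if (grepl(",", cv)) {
            nums <- as.numeric(strsplit(cv, ",", fixed = TRUE)[[1L]])
            if (length(nums) != 3L || anyNA(nums))
              stop("phage ", words[[2L]],
                   ": lysogeny_curve must be a preset name or p_max,K,h")
            curve <- lysogeny_curve(nums[1L], nums[2L], nums[3L])
          } else curve <- lysogeny_preset(cv)
        } else stop("phage ", words[[2L]], ": undefined lysogeny curve: ", cv)
      }
      spec_args <- kv[setdiff(names(kv), c("count", "lysogeny_curve"))]
      sp <- do.call(phage_species,
                    c(list(name = words[[2L]], lysogeny_curve = curve),
                      spec_args))
      phages[[length(phages) + 1L]] <-
        list(species = sp, count = if (is.null(kv$count)) 0L else kv$count)
    } else if (kind %in% c("host_range", "superinfection")) {
      m <- parse_matrix_block(sec$lines, kind, basename(path))
      if (kind == "host_range") host_range <- m else superinfection <- m
    } else stop(basename(path), ": unknown section [", sec$name, "]")
  }
  if (is.null(host_range)) stop(basename(path), ": missing [host_range] section")
  eco_setup(bacteria = bacteria, phages = phages, phenotypes = phenotypes,
            host_range = host_range, superinfection = superinfection)
}

# whitespace-delimited matrix block: first row = column labels, following
# rows = row label then entries
parse_matrix_block <- function(lines, what, file) {
  lines <- trimws(vapply(lines, strip_comment, "", USE.NAMES = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(file, ": [", what, "] block is empty")
  cols <- strsplit(lines[[1L]], "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(ln) strsplit(ln, "\\s+")[[1L]])
  bad <- vapply(rows, length, 0L) != length(cols) + 1L
  if (any(bad))
    stop(file, ": [", what, "] row has wrong number of entries: ",
         lines[-1L][bad][1L])
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  dimnames(m) <- list(vapply(rows, `[[`, "", 1L), cols)
  if (anyNA(m)) stop(file, ": [", what, "] contains non-numeric entries")
  m
}

# serialization -----------------------------------------------------------------

fmt_scalar <- function(x) {
  if (is.null(x)) "none"
  else if (is.logical(x)) tolower(as.character(x))
  else as.character(x)
}

#' Write a general-parameter file
#'
#' @param general A [general_params()] list.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_general_params <- function(general, path) {
  keys <- names(general_param_defaults())
  lines <- vapply(keys, function(k)
    paste(k, "=", fmt_scalar(general[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an ecological-setup file
#'
#' @param eco An [eco_setup()] list.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_eco_setup <- function(eco, path) {
  out <- c("[phenotypes]", paste(eco$phenotypes, collapse = " "), "")
  for (b in eco$bacteria) {
    sp <- b$species
    out <- c(out, paste0("[bacterium ", sp$name, "]"),
             paste("count =", b$count),
             paste("base_growth_rate =", sp$base_growth_rate))
    if (!is.null(sp$intrinsic_death_prob))
      out <- c(out, paste("intrinsic_death_prob =", sp$intrinsic_death_prob))
    out <- c(out,
             paste("antibiotic_resistant =", fmt_scalar(sp$antibiotic_resistant)),
             if (length(sp$phage_resistance_profile))
               paste("phage_resistance_profile =",
                     paste(sp$phage_resistance_profile, collapse = " ")),
             paste("cost_antibiotic_resistance =", sp$cost_antibiotic_resistance),
             paste("cost_phage_resistance =", sp$cost_phage_resistance),
             paste("mu_antibiotic =", sp$mu_antibiotic),
             paste("mu_phage_receptor =", sp$mu_phage_receptor),
             if (length(b$prophages))
               paste("prophages =",
                     paste(vapply(b$prophages, function(p)
                       paste0(p$species, ":", p$attachment_phenotype), ""),
                       collapse = " ")),
             "")
  }
  for (p in eco$phages) {
    sp <- p$species
    out <- c(out, paste0("[phage ", sp$name, "]"),
             paste("count =", p$count),
             paste("lifestyle =", sp$lifestyle),
             paste("attachment_phenotype =", sp$attachment_phenotype),
             paste("burst_size =", sp$burst_size),
             paste("adsorption_prob =", sp$adsorption_prob),
             paste("decay_prob =", sp$decay_prob),
             paste("mu_attachment =", sp$mu_attachment),
             paste("induction_prob =", sp$induction_prob),
             paste("stress_induction_factor =", sp$stress_induction_factor),
             if (!is.null(sp$lysogeny_curve))
               paste("lysogeny_curve =",
                     if (sp$lysogeny_curve$preset_name != "custom")
                       sp$lysogeny_curve$preset_name
                     else paste(sp$lysogeny_curve$p_max,
                                sp$lysogeny_curve$half_density,
                                sp$lysogeny_curve$hill_exponent, sep = ",")),
             "")
  }
  write_matrix_block <- function(m, name) {
    c(paste0("[", name, "]"),
      paste(colnames(m), collapse = " "),
      vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], m[i, ]), collapse = " "), ""),
      "")
  }
  reg <- build_registry(eco)
  out <- c(out, write_matrix_block(reg$host_range, "host_range"))
  if (length(eco$phages))
    out <- c(out, write_matrix_block(reg$superinfection, "superinfection"))
  writeLines(out[!vapply(out, is.null, TRUE)], path)
  invisible(path)
}

# trajectory / snapshot IO -------------------------------------------------------

#' Write a trajectory to delimited text
#'
#' Tab-separated with a header; trajectory metadata (lattice size, species
#' lists, seed) is preserved in `#meta` comment lines so that
#' [read_trajectory()] round-trips the object.
#'
#' @param trajectory A `phage_trajectory` from [run_simulation()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  meta <- attr(trajectory, "meta")
  hdr <- vapply(names(meta), function(k)
    paste0("#meta ", k, "\t", paste(meta[[k]], collapse = "\t")), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(trajectory), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @return A `phage_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#meta ", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#meta ")]
  traj <- utils::read.table(text = body, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^#meta ", "", ln), "\t", fixed = TRUE)[[1L]]
    key <- parts[[1L]]
    vals <- parts[-1L]
    nums <- suppressWarnings(as.numeric(vals))
    meta[[key]] <- if (!anyNA(nums)) {
      if (all(nums == as.integer(nums))) as.integer(nums) else nums
    } else vals
  }
  class(traj) <- c("phage_trajectory", "data.frame")
  attr(traj, "meta") <- meta
  traj
}

#' Write a lattice snapshot
#'
#' One row per occupied location and layer: `iteration`, `x`, `y` (0-based;
#' `x` is the column), `layer` (`bacterium`, `phage` or `antibiotic`),
#' `label` (genotype, `species:phenotype`, or `concentration`) and `value`
#' (1 for a bacterium, the virion count for a phage row, the concentration
#' for an antibiotic row).
#'
#' @param state A [simulation_state()].
#' @param path Destination file.
#' @param append Append to an existing snapshot file (the header is written
#'   only when starting a new file).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path, append = FALSE) {
  cfg <- state$config
  cache <- new.env(parent = emptyenv())
  rows <- list()
  occ <- which(state$b_species != 0L)
  if (length(occ))
    rows[[1L]] <- data.frame(
      x = loc_x(occ, cfg), y = loc_y(occ, cfg), layer = "bacterium",
      label = genotype_labels_for(state, occ, cache), value = 1)
  if (length(state$p_loc)) {
    reg <- state$registry
    key <- paste(state$p_loc,
                 paste0(names(reg$phages)[state$p_species], ":",
                        reg$phenotypes[state$p_pheno]), sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    locs <- as.integer(vapply(parts, `[[`, "", 1L))
    rows[[length(rows) + 1L]] <- data.frame(
      x = loc_x(locs, cfg), y = loc_y(locs, cfg), layer = "phage",
      label = vapply(parts, `[[`, "", 2L), value = as.numeric(tab))
  }
  hot <- which(state$field$conc > 0)
  if (length(hot))
    rows[[length(rows) + 1L]] <- data.frame(
      x = loc_x(hot, cfg), y = loc_y(hot, cfg), layer = "antibiotic",
      label = "concentration", value = state$field$conc[hot])
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(x = integer(0), y = integer(0), layer = character(0),
                  label = character(0), value = numeric(0))
  df <- cbind(iteration = state$iter, df)
  write_header <- !append || !file.exists(path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = write_header,
                       append = append && file.exists(path)))
  invisible(path)
}
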