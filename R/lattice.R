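# Lattice geometry and the antibiotic field.
#
# Locations are 1-based linear indices over a width x height grid:
#   x = (i - 1) %% width   (column, 0-based)
#   y = (i - 1) %/% width  (row, 0-based)
# Neighborhoods are Moore neighborhoods (Chebyshev distance).

#' Lattice configuration
#'
#' Defines the 2-D environment: its dimensions, boundary topology, degree of
#' spatial structure, and the radii governing offspring placement and virion
#' diffusion.
#'
#' Structure modes:
#' \describe{
#'   \item{well_mixed}{the contents of every location (bacteria and free
#'     virions) are randomized at each iteration, emulating liquid culture;
#'     competition for free space is then local at radius 1.}
#'   \item{semi_structured}{bacteria stay in place but offspring can be placed
#'     within `reproduction_radius`; virions diffuse within
#'     `phage_diffusion_radius`.}
#'   \item{structured}{bacteria never relocate and offspring placement is
#'     restricted to the adjacent (radius-1) Moore neighborhood.}
#' }
#'
#' @param width,height Grid dimensions (each at least 2).
#' @param topology `"bounded"` (edges clip neighborhoods) or `"toroidal"`
#'   (coordinates wrap).
#' @param structure One of `"well_mixed"`, `"semi_structured"`, `"structured"`.
#' @param reproduction_radius Moore distance for offspring placement under
#'   semi-structure (integer >= 1). Forced to 1 when `structure = "structured"`.
#' @param phage_diffusion_radius Moore distance within which a free virion can
#'   move in one iteration (integer >= 0).
#' @param phage_cap_per_location Maximum number of free virions a location can
#'   hold (integer >= 1).
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(width = 50L, height = 50L,
                           topology = c("bounded", "toroidal"),
                           structure = c("well_mixed", "semi_structured", "structured"),
                           reproduction_radius = 3L,
                           phage_diffusion_radius = 3L,
                           phage_cap_per_location = 50L) {
  topology <- match.arg(topology)
  structure <- match.arg(structure)
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || width < 2L) stop("width must be an integer >= 2")
  if (is.na(height) || height < 2L) stop("height must be an integer >= 2")
  reproduction_radius <- as.integer(reproduction_radius)
  phage_diffusion_radius <- as.integer(phage_diffusion_radius)
  phage_cap_per_location <- as.integer(phage_cap_per_location)
  if (is.na(reproduction_radius) || reproduction_radius < 1L)
    stop("reproduction_radius must be an integer >= 1")
  if (is.na(phage_diffusion_radius) || phage_diffusion_radius < 0L)
    stop("phage_diffusion_radius must be an integer >= 0")
  if (is.na(phage_cap_per_location) || phage_cap_per_location < 1L)
    stop("phage_cap_per_location must be an integer >= 1")
  if (structure == "structured") reproduction_radius <- 1L
  structure(
    list(width = width, height = height, topology = topology,
         structure = structure, reproduction_radius = reproduction_radius,
         phage_diffusion_radius = phage_diffusion_radius,
         phage_cap_per_location = phage_cap_per_location),
    class = "lattice_config")
}

n_locations <- function(config) config$width * config$height

loc_x <- function(i, config) (i - 1L) %% config$width
loc_y <- function(i, config) (i - 1L) %/% config$width
loc_index <- function(x, y, config) x + y * config$width + 1L

#' Moore neighborhood of a location
#'
#' All distinct locations at Chebyshev distance 1..`radius` from `location`.
#' The focal location is excluded. Bounded topology drops off-grid
#' coordinates; toroidal topology wraps them.
#'
#' @param location Integer vector `c(x, y)` of 0-based grid coordinates.
#' @param radius Moore distance (integer >= 0); radius 0 gives an empty set.
#' @param config A [lattice_config()].
#' @return An integer matrix with columns `x` and `y`, one row per neighbor.
#' @export
neighborhood <- function(location, radius, config) {
  stopifnot(length(location) == 2L)
  x <- as.integer(location[[1L]]); y <- as.integer(location[[2L]])
  if (x < 0L || x >= config$width || y < 0L || y >= config$height)
    stop("location (", x, ",", y, ") outside lattice")
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  if (radius == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[!(offs$dx == 0L & offs$dy == 0L), , drop = FALSE]
  nx <- x + offs$dx; ny <- y + offs$dy
  if (config$topology == "toroidal") {
    nx <- nx %% config$width; ny <- ny %% config$height
  } else {
    keep <- nx >= 0L & nx < config$width & ny >= 0L & ny < config$height
    nx <- nx[keep]; ny <- ny[keep]
  }
  m <- unique(cbind(x = as.integer(nx), y = as.integer(ny)))
  rownames(m) <- NULL
  m
}

# Precomputed neighbor index table: N x m integer matrix where m = (2r+1)^2 - 1.
# Off-grid neighbors (bounded topology) hold the sentinel N + 1, so gathers on
# a vector padded with one extra element are branch-free. attr "n_valid" gives
# the per-row count of real neighbors.
build_neighbor_index <- function(config, radius) {
  N <- n_locations(config)
  if (radius == 0L) {
    m <- matrix(integer(0), nrow = N, ncol = 0L)
    attr(m, "n_valid") <- integer(N)
    return(m)
  }
  W <- config$width; H <- config$height
  xs <- (seq_len(N) - 1L) %% W
  ys <- (seq_len(N) - 1L) %/% W
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[!(offs$dx == 0L & offs$dy == 0L), , drop = FALSE]
  m <- matrix(N + 1L, nrow = N, ncol = nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nx <- xs + offs$dx[k]; ny <- ys + offs$dy[k]
    if (config$topology == "toroidal") {
      nx <- nx %% W; ny <- ny %% H
      m[, k] <- nx + ny * W + 1L
    } else {
      valid <- nx >= 0L & nx < W & ny >= 0L & ny < H
      m[valid, k] <- nx[valid] + ny[valid] * W + 1L
    }
  }
  attr(m, "n_valid") <- as.integer(rowSums(m <= N))
  m
}

# Sum (or count) a per-location quantity over the radius-1 Moore neighborhood,
# excluding the focal location. `values` has length N.
neighbor_sum <- function(values, nbr) {
  v <- c(values, 0)
  out <- numeric(length(values))
  for (k in seq_len(ncol(nbr))) out <- out + v[nbr[, k]]
  out
}

#' Antibiotic concentration field
#'
#' A per-location antibiotic concentration (arbitrary dose units) together
#' with the constants governing its dynamics: a per-iteration degradation
#' fraction, a per-iteration diffusion fraction redistributed to the radius-1
#' Moore neighbors, and the deployment rule used when a dose is applied.
#'
#' @param config A [lattice_config()].
#' @param degradation_rate Fraction of concentration lost per iteration, in
#'   \[0,1\].
#' @param diffusion_fraction Fraction of each location's concentration
#'   redistributed to its Moore-1 neighbors per iteration, in \[0,1\].
#' @param deployment_mode `"homogeneous"` (every location receives the dose)
#'   or `"heterogeneous"` (`n_foci` random locations receive it).
#' @param n_foci Number of deployment foci in heterogeneous mode.
#' @param dose Concentration applied at deployed locations (>= 0).
#' @return An object of class `antibiotic_field` with a `conc` vector of
#'   length `width * height`.
#' @export
antibiotic_field <- function(config, degradation_rate = 0.01,
                             diffusion_fraction = 0.2,
                             deployment_mode = c("homogeneous", "heterogeneous"),
                             n_foci = 10L, dose = 10) {
  deployment_mode <- match.arg(deployment_mode)
  if (degradation_rate < 0 || degradation_rate > 1)
    stop("degradation_rate must be in [0,1]")
  if (diffusion_fraction < 0 || diffusion_fraction > 1)
    stop("diffusion_fraction must be in [0,1]")
  if (dose < 0) stop("dose must be >= 0")
  n_foci <- as.integer(n_foci)
  if (deployment_mode == "heterogeneous" &&
      (n_foci < 1L || n_foci > n_locations(config)))
    stop("n_foci must be between 1 and width*height")
  structure(
    list(conc = numeric(n_locations(config)),
         degradation_rate = degradation_rate,
         diffusion_fraction = diffusion_fraction,
         deployment_mode = deployment_mode,
         n_foci = n_foci, dose = dose),
    class = "antibiotic_field")
}

#' Deploy an antibiotic dose
#'
#' Homogeneous mode sets every location to `dose`; heterogeneous mode sets
#' `n_foci` distinct, uniformly chosen locations to `dose` and leaves the rest
#' unchanged.
#'
#' @param field An [antibiotic_field()].
#' @param config The matching [lattice_config()].
#' @return The updated field.
#' @export
deploy_antibiotic <- function(field, config) {
  N <- n_locations(config)
  if (field$dose < 0) stop("dose must be >= 0")
  if (field$deployment_mode == "homogeneous") {
    field$conc[] <- field$dose
  } else {
    if (field$n_foci > N) stop("n_foci exceeds grid size")
    foci <- sample.int(N, field$n_foci)
    field$conc[foci] <- field$dose
  }
  field
}

#' One iteration of antibiotic diffusion and degradation
#'
#' Each location keeps `1 - diffusion_fraction` of its concentration and sends
#' `diffusion_fraction / 8` to each of its Moore-1 neighbors; on bounded grids
#' the share that would leave the lattice stays in place, so total mass is
#' conserved by diffusion under both topologies. All concentrations are then
#' multiplied by `1 - degradation_rate`.
#'
#' @param field An [antibiotic_field()].
#' @param config The matching [lattice_config()].
#' @param nbr Optional precomputed radius-1 neighbor index table (built
#'   internally when missing).
#' @return The updated field; concentrations stay nonnegative.
#' @export
update_antibiotic <- function(field, config, nbr = NULL) {
  conc <- field$conc
  if (any(conc > 0) && field$diffusion_fraction > 0) {
    if (is.null(nbr)) nbr <- build_neighbor_index(config, 1L)
    share <- conc * field$diffusion_fraction / 8
    out <- share * attr(nbr, "n_valid")
    conc <- conc - out + neighbor_sum(share, nbr)
  }
  conc <- conc * (1 - field$degradation_rate)
  conc[conc < 0] <- 0  # guard against roundoff
  field$conc <- conc
  field
}

total_antibiotic_mass <- function(field) sum(field$conc)
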