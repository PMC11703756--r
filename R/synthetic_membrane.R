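#' Parameters for the bilayer-mimetic Langevin simulator
#'
#' The simulator propagates membrane-embedded solutes (ionophore-like
#' molecules) with overdamped Langevin dynamics. Along the membrane normal
#' each solute feels a quartic double well
#' \deqn{U(z) = \Delta E \,\left[(z/z_0)^2 - 1\right]^2}
#' whose minima at \eqn{\pm z_0} are the two leaflet positions and whose
#' barrier at the membrane centre (\eqn{z = 0}) has height `barrier_height`
#' (kT). Lateral motion is diffusive in a periodic box. All energies are in
#' kT, lengths in nm, times in ns.
#'
#' @param well_position_z0 leaflet equilibrium distance from the membrane
#'   centre (nm, > 0).
#' @param barrier_height central barrier \eqn{\Delta E} in kT (>= 0).
#' @param lateral_diffusion,normal_diffusion diffusion coefficients
#'   (nm^2/ns, > 0).
#' @param timestep integration step (ns). Must be small enough that the RMS
#'   single-step normal displacement is below `well_position_z0 / 5`.
#' @param n_steps number of integration steps.
#' @param frame_stride emit a trajectory frame every this many steps (>= 1).
#' @param box_xy lateral box edge (nm, periodic). The default 6.3 nm puts two
#'   solutes at a two-dimensional density of ~0.05 molecules/nm^2, the density
#'   the membrane system emulates.
#' @param box_z box height (nm); must exceed `4 * well_position_z0`. z is
#'   never wrapped.
#' @param head_group_z distance of the static phosphate reference sheets from
#'   the membrane centre (nm).
#' @return an object of class `langevin_params`.
#' @export
langevin_params <- function(well_position_z0 = 1.0, barrier_height = 8,
                            lateral_diffusion = 0.1, normal_diffusion = 0.1,
                            timestep = 0.01, n_steps = 200000L,
                            frame_stride = 10L, box_xy = 6.3, box_z = 6.0,
                            head_group_z = 1.9) {
  assert_scalar_num(well_position_z0, "well_position_z0", 0, strict = TRUE)
  assert_scalar_num(barrier_height, "barrier_height", 0)
  assert_scalar_num(lateral_diffusion, "lateral_diffusion", 0, strict = TRUE)
  assert_scalar_num(normal_diffusion, "normal_diffusion", 0, strict = TRUE)
  assert_scalar_num(timestep, "timestep", 0, strict = TRUE)
  assert_scalar_num(box_xy, "box_xy", 0, strict = TRUE)
  if (box_z <= 4 * well_position_z0)
    stop_ld("box_z must exceed 4 * well_position_z0 (= %.2f nm)",
            4 * well_position_z0)
  step_rms <- sqrt(2 * normal_diffusion * timestep)
  if (step_rms >= well_position_z0 / 5)
    stop_ld(paste0("unstable integration: RMS single-step z displacement ",
                   "%.3f nm >= well_position_z0/5 = %.3f nm; reduce timestep"),
            step_rms, well_position_z0 / 5)
  n_steps <- as.integer(n_steps)
  frame_stride <- as.integer(frame_stride)
  if (n_steps < 1L || frame_stride < 1L)
    stop_ld("n_steps and frame_stride must be positive integers")
  structure(list(well_position_z0 = well_position_z0,
                 barrier_height = barrier_height,
                 lateral_diffusion = lateral_diffusion,
                 normal_diffusion = normal_diffusion,
                 timestep = timestep, n_steps = n_steps,
                 frame_stride = frame_stride, box_xy = box_xy, box_z = box_z,
                 head_group_z = head_group_z),
            class = "langevin_params")
}

#' Simulation composition: species counts, thresholds and pair interactions
#'
#' Describes which solute species are present, how many of each, the
#' per-species flip-flop confirmation thresholds, and the pairwise
#' interaction matrix. For every unordered species pair the interaction is
#' `(epsilon, sigma_r, sigma_z, kappa)`:
#' \itemize{
#'   \item `epsilon` (kT, >= 0): coupling strength. Raises each partner's
#'     mid-membrane barrier by `epsilon * exp(-r^2/2 sigma_r^2) *
#'     exp(-z^2/2 sigma_z^2)` and attracts the pair laterally through
#'     `-epsilon * exp(-r^2/2 sigma_r^2)`, producing the clustering and
#'     transition suppression seen for membrane-embedded ionophores.
#'   \item `sigma_r`, `sigma_z` (nm): lateral and normal interaction ranges.
#'   \item `kappa` (kT/nm, >= 0): peripheral-shift bias, an outward force
#'     `kappa * exp(-r^2/2 sigma_r^2) * sign(z)` pushing paired molecules
#'     towards the head groups.
#' }
#'
#' @param counts named integer vector, solutes per species,
#'   e.g. `c(A = 1, B = 1)`.
#' @param thresholds named numeric vector of per-species confirmation
#'   distances d (nm). Defaults `A = 0.7`, `B = 0.6`; any other species must
#'   be given explicitly.
#' @param interactions list of interaction specs. Each element is a list with
#'   fields `pair` (character 2-vector of species), `epsilon`, `sigma_r`,
#'   `sigma_z`, `kappa`. Pairs not listed do not interact.
#' @return an object of class `sim_composition`.
#' @export
sim_composition <- function(counts, thresholds = c(A = 0.7, B = 0.6),
                            interactions = list()) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_ld("'counts' must be a named vector of per-species solute counts")
  counts <- vapply(counts, function(x) as.integer(x), integer(1))
  if (any(counts < 0L)) stop_ld("species counts must be >= 0")
  if (sum(counts) < 1L) stop_ld("total particle count must be >= 1")
  species <- names(counts)[counts > 0L]
  missing_d <- setdiff(species, names(thresholds))
  if (length(missing_d))
    stop_ld("no transition threshold configured for species: %s",
            paste(missing_d, collapse = ", "))
  if (any(thresholds[species] <= 0))
    stop_ld("transition thresholds must be > 0 nm")
  for (ia in interactions) {
    need <- c("pair", "epsilon", "sigma_r", "sigma_z")
    if (!all(need %in% names(ia)))
      stop_ld("each interaction needs fields: %s", paste(need, collapse = ", "))
    if (length(ia$pair) != 2L)
      stop_ld("interaction 'pair' must name two species")
    if (ia$epsilon < 0) stop_ld("interaction epsilon must be >= 0")
    if (ia$sigma_r <= 0 || ia$sigma_z <= 0)
      stop_ld("interaction ranges must be > 0")
  }
  structure(list(counts = counts, thresholds = thresholds,
                 interactions = interactions),
            class = "sim_composition")
}

# expand composition into per-particle vectors + species-indexed matrices
.comp_tables <- function(comp) {
  counts <- comp$counts[comp$counts > 0L]
  species <- names(counts)
  n_sp <- length(species)
  species_of <- rep(species, counts)
  mat <- function() matrix(0, n_sp, n_sp, dimnames = list(species, species))
  eps <- mat(); sr <- mat(); sz <- mat(); kap <- mat()
  for (ia in comp$interactions) {
    p <- ia$pair
    if (!all(p %in% species)) next
    i <- match(p[1], species); j <- match(p[2], species)
    eps[i, j] <- eps[j, i] <- ia$epsilon
    sr[i, j] <- sr[j, i] <- ia$sigma_r
    sz[i, j] <- sz[j, i] <- ia$sigma_z
    kap[i, j] <- kap[j, i] <- ia$kappa %||% 0
  }
  list(species = species, species_of = species_of,
       thresholds = as.numeric(comp$thresholds[species]),
       eps = eps, sigma_r = sr, sigma_z = sz, kappa = kap)
}

#' Simulate solute trajectories in a bilayer-mimetic double well
#'
#' Runs the overdamped Langevin model described in [langevin_params()] and
#' [sim_composition()] and returns both a [trajectory] (at `frame_stride`
#' resolution, including two static phosphate reference sheets so the
#' membrane-centre computation of the analysis layer is exercised) and the
#' generator's ground truth computed at full step resolution: true transition
#' times (threshold-excursion sign changes, the same criterion as
#' [detect_transitions()]), leaflet occupancy fractions, and pair contact
#' fractions (lateral minimum-image distance within `2 sigma_r`).
#'
#' Solutes start laterally uniform in the box with z drawn uniformly from the
#' two well positions \eqn{\pm z_0}.
#'
#' @param params a [langevin_params()] object.
#' @param comp a [sim_composition()] object.
#' @param seed integer seed; identical `(params, comp, seed)` give
#'   bit-identical output.
#' @return list with elements `trajectory` (a `trajectory` object),
#'   `ztraces` (data frame: `time_ns`, `molecule_id`, `species`, `z_nm`, at
#'   frame resolution) and `ground_truth` (list: per-particle
#'   `transitions` with `time_ns`/`direction`, `occupancy` data frame,
#'   `contact_fraction` matrix, `observation_ns`).
#' @export
simulate_solute_trajectories <- function(params, comp, seed) {
  stopifnot(inherits(params, "langevin_params"),
            inherits(comp, "sim_composition"))
  tab <- .comp_tables(comp)
  n <- length(tab$species_of)
  max_sr <- max(tab$sigma_r, 0)
  if (3 * max_sr >= params$box_xy / 2)
    stop_ld("box_xy/2 must exceed the interaction truncation range 3*sigma_r")
  set.seed(as.integer(seed))
  x0 <- runif(n, 0, params$box_xy)
  y0 <- runif(n, 0, params$box_xy)
  z0v <- sample(c(-1, 1), n, replace = TRUE) * params$well_position_z0
  sp_idx <- match(tab$species_of, tab$species) - 1L

  res <- langevin_core(sp_idx, tab$thresholds, tab$eps, tab$sigma_r,
                       tab$sigma_z, tab$kappa,
                       params$well_position_z0, params$barrier_height,
                       params$lateral_diffusion, params$normal_diffusion,
                       params$timestep, params$n_steps, params$frame_stride,
                       params$box_xy, params$box_xy, x0, y0, z0v)

  n_frames <- length(res$times)
  # static phosphate reference sheets at +/- head_group_z (4x4 grid each)
  g <- seq(params$box_xy / 8, params$box_xy, by = params$box_xy / 4)
  grid <- expand.grid(x = g, y = g)
  n_ref <- 2L * nrow(grid)
  ref_xyz <- rbind(cbind(grid$x, grid$y, params$head_group_z),
                   cbind(grid$x, grid$y, -params$head_group_z))

  coords <- array(NA_real_, dim = c(n + n_ref, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[seq_len(n), 1, f] <- res$frames_x[f, ]
    coords[seq_len(n), 2, f] <- res$frames_y[f, ]
    coords[seq_len(n), 3, f] <- res$frames_z[f, ]
    coords[n + seq_len(n_ref), , f] <- ref_xyz
  }
  topo <- data.frame(
    molecule_id = c(seq_len(n), 1000L + seq_len(n_ref)),
    species = c(tab$species_of, rep("P", n_ref)),
    atom_name = c(rep("COM", n), rep("P", n_ref)),
    mass = c(rep(1, n), rep(30.97, n_ref)),
    stringsAsFactors = FALSE)
  traj <- trajectory(times = res$times, coords = coords,
                     box = c(params$box_xy, params$box_xy, params$box_z),
                     topology = topo)

  zt <- data.frame(
    time_ns = rep(res$times, times = n),
    molecule_id = rep(seq_len(n), each = n_frames),
    species = rep(tab$species_of, each = n_frames),
    z_nm = as.numeric(res$frames_z))

  transitions <- lapply(seq_len(n), function(i) {
    tr <- res$transitions[[i]]
    data.frame(time_ns = tr$time_ns,
               direction = ifelse(tr$direction > 0, "up", "down"))
  })
  names(transitions) <- paste0(tab$species_of, seq_len(n))
  occupancy <- data.frame(molecule_id = seq_len(n), species = tab$species_of,
                          upper = res$occupancy_upper,
                          lower = res$occupancy_lower)
  contact <- res$contact_steps / params$n_steps
  contact <- contact + t(contact)
  dimnames(contact) <- list(seq_len(n), seq_len(n))

  list(trajectory = traj, ztraces = zt,
       ground_truth = list(transitions = transitions,
                           transition_counts = vapply(transitions, nrow,
                                                      integer(1)),
                           occupancy = occupancy,
                           contact_fraction = contact,
                           observation_ns = params$n_steps * params$timestep))
}
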