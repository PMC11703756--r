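#' Radial distribution function between two solute species
#'
#' Histograms minimum-image pair distances between species `a` and `b` across
#' frames and normalizes by the ideal-gas expectation at the same particle
#' density and geometry, so that a structureless uniform system gives
#' `g(r) = 1`. Two metrics are available: `full_3d` (Euclidean distance,
#' box treated as periodic in all three directions) and `lateral_2d`
#' (in-plane distance, z ignored — the in-leaflet view). The finite-size
#' normalization uses the number of eligible ordered pairs (i.e. `N - 1`
#' partners per reference particle for like pairs). Conditioning restricts
#' the counted pairs to those in the same or in opposite leaflets
#' (instantaneous sign of z relative to the phosphate membrane centre);
#' the normalization then uses the eligible-pair count after filtering, so a
#' uniform system still gives 1.
#'
#' @param traj a [trajectory] object.
#' @param species_pair character 2-vector, e.g. `c("A", "A")`.
#' @param mode `"full_3d"` (default) or `"lateral_2d"`.
#' @param bin_width histogram bin width (nm, default 0.05).
#' @param r_max maximum distance (nm); defaults to half the smallest box
#'   edge of the chosen metric, and must not exceed it.
#' @param conditioning `"none"`, `"same_leaflet"` or `"opposite_leaflet"`.
#' @param reference_species membrane-centre reference for leaflet
#'   conditioning (default `"P"`; ignored for `conditioning = "none"`).
#' @return object of class `rdf_result`: `r` (bin centres), `g`,
#'   `pair_count` per bin, `n_pairs_total` (eligible ordered pairs summed
#'   over frames), `mode`, `empty` (TRUE when conditioning removed every
#'   pair — then `g` is all `NA`).
#' @export
radial_distribution <- function(traj, species_pair,
                                mode = c("full_3d", "lateral_2d"),
                                bin_width = 0.05, r_max = NULL,
                                conditioning = c("none", "same_leaflet",
                                                 "opposite_leaflet"),
                                reference_species = "P") {
  mode <- match.arg(mode)
  conditioning <- match.arg(conditioning)
  stopifnot(length(species_pair) == 2L)
  ia <- select_particles(traj, species = species_pair[1])
  ib <- select_particles(traj, species = species_pair[2])
  if (!length(ia) || !length(ib))
    stop_ld("species '%s' and '%s' must both be present",
            species_pair[1], species_pair[2])
  like <- species_pair[1] == species_pair[2]
  if (like && length(ia) < 2L)
    stop_ld("need >= 2 particles of species '%s' for a like-pair RDF",
            species_pair[1])
  box <- traj$box
  half <- if (mode == "lateral_2d") min(box[1:2]) / 2 else min(box) / 2
  r_max <- r_max %||% half
  if (r_max > half + 1e-9)
    stop_ld("r_max (%.3f nm) exceeds half the smallest box edge (%.3f nm)",
            r_max, half)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  n_pairs_total <- 0
  need_leaflet <- conditioning != "none"
  ref <- if (need_leaflet) select_particles(traj,
                                            species = reference_species)
  if (need_leaflet && !length(ref))
    stop_ld("leaflet conditioning needs reference species '%s'",
            reference_species)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xa <- matrix(traj$coords[ia, , f], ncol = 3L)
    xb <- matrix(traj$coords[ib, , f], ncol = 3L)
    pair_ok <- matrix(TRUE, length(ia), length(ib))
    if (like) diag(pair_ok) <- FALSE
    if (need_leaflet) {
      zc <- compute_com(traj, f, ref)[3]
      sa <- sign(xa[, 3] - zc); sb <- sign(xb[, 3] - zc)
      rel <- outer(sa, sb, `*`)
      pair_ok <- pair_ok & if (conditioning == "same_leaflet") rel > 0
                           else rel < 0
    }
    if (!any(pair_ok)) next
    dx <- outer(xa[, 1], xb[, 1], `-`); dx <- dx - box[1] * round(dx / box[1])
    dy <- outer(xa[, 2], xb[, 2], `-`); dy <- dy - box[2] * round(dy / box[2])
    if (mode == "lateral_2d") {
      r <- sqrt(dx^2 + dy^2)
    } else {
      dz <- outer(xa[, 3], xb[, 3], `-`)
      dz <- dz - box[3] * round(dz / box[3])
      r <- sqrt(dx^2 + dy^2 + dz^2)
    }
    n_pairs_total <- n_pairs_total + sum(pair_ok)
    r <- r[pair_ok & r <= r_max]
    if (length(r))
      counts <- counts + tabulate(findInterval(r, breaks,
                                               rightmost.closed = TRUE,
                                               all.inside = TRUE),
                                  nbins = nb)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (n_pairs_total == 0) {
    return(structure(list(r = mids, g = rep(NA_real_, nb),
                          pair_count = counts, n_pairs_total = 0,
                          mode = mode, conditioning = conditioning,
                          bin_width = bin_width, empty = TRUE),
                     class = "rdf_result"))
  }
  shell <- if (mode == "lateral_2d") {
    pi * diff(breaks^2) / (box[1] * box[2])
  } else {
    (4 / 3) * pi * diff(breaks^3) / prod(box)
  }
  expected <- n_pairs_total * shell
  structure(list(r = mids, g = counts / expected, pair_count = counts,
                 n_pairs_total = n_pairs_total, mode = mode,
                 conditioning = conditioning, bin_width = bin_width,
                 empty = FALSE),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  if (x$empty) {
    cat("rdf_result: empty (no eligible pairs after conditioning)\n")
  } else {
    cat(sprintf("rdf_result (%s%s): %d bins to %.2f nm, %g ordered pairs\n",
                x$mode,
                if (x$conditioning != "none") paste0(", ", x$conditioning)
                else "",
                length(x$r), max(x$r) + x$bin_width / 2, x$n_pairs_total))
  }
  invisible(x)
}

.pair_dist_matrix <- function(xyz, box, mode) {
  dx <- outer(xyz[, 1], xyz[, 1], `-`); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(xyz[, 2], xyz[, 2], `-`); dy <- dy - box[2] * round(dy / box[2])
  if (mode == "lateral_2d") return(sqrt(dx^2 + dy^2))
  dz <- outer(xyz[, 3], xyz[, 3], `-`); dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Cutoff clustering of solutes in one frame
#'
#' Particles are clustered as the connected components of the graph whose
#' edges join particles at minimum-image distance `<= cutoff`. The default
#' cutoff of 1 nm reflects where membrane-embedded ionophore RDFs deviate
#' strongly from unity.
#'
#' @param traj a [trajectory] object.
#' @param frame frame index.
#' @param species character vector of species to cluster (must be
#'   non-empty and present).
#' @param cutoff linking distance (nm, > 0).
#' @param mode distance metric, `"lateral_2d"` (default: in-membrane
#'   clustering) or `"full_3d"`.
#' @return object of class `cluster_result`: `labels` (cluster id per
#'   selected particle, named by particle index), `sizes` (per cluster),
#'   `n_clusters`, `largest`.
#' @export
detect_clusters <- function(traj, frame = 1L, species, cutoff = 1.0,
                            mode = c("lateral_2d", "full_3d")) {
  mode <- match.arg(mode)
  assert_scalar_num(cutoff, "cutoff", 0, strict = TRUE)
  if (missing(species) || !length(species))
    stop_ld("'species' subset must be non-empty")
  sel <- select_particles(traj, species = species)
  if (!length(sel)) stop_ld("no particles of species: %s",
                            paste(species, collapse = ", "))
  xyz <- matrix(traj$coords[sel, , frame], ncol = 3L)
  dm <- .pair_dist_matrix(xyz, traj$box, mode)
  adj <- (dm <= cutoff)
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  labels <- setNames(comp$membership, sel)
  structure(list(labels = labels, sizes = as.integer(comp$csize),
                 n_clusters = comp$no, largest = max(comp$csize),
                 cutoff = cutoff, mode = mode),
            class = "cluster_result")
}

#' Cluster statistics aggregated over all frames
#'
#' Runs [detect_clusters()] on every frame and aggregates: the largest
#' cluster size per frame, the pooled cluster-size distribution, and for
#' each k the fraction of frames containing any cluster of size `>= k`.
#'
#' @inheritParams detect_clusters
#' @return list: `largest_by_frame`, `mean_largest`, `size_distribution`
#'   (data frame size/count), `frac_frames_ge` (named numeric, k = 1..N).
#' @export
cluster_timeseries <- function(traj, species, cutoff = 1.0,
                               mode = c("lateral_2d", "full_3d")) {
  mode <- match.arg(mode)
  if (missing(species) || !length(species))
    stop_ld("'species' subset must be non-empty")
  nf <- n_frames(traj)
  largest <- integer(nf)
  all_sizes <- integer(0)
  for (f in seq_len(nf)) {
    cl <- detect_clusters(traj, f, species, cutoff, mode)
    largest[f] <- cl$largest
    all_sizes <- c(all_sizes, cl$sizes)
  }
  tab <- table(all_sizes)
  n_sel <- length(select_particles(traj, species = species))
  frac <- vapply(seq_len(n_sel), function(k) mean(largest >= k), numeric(1))
  list(largest_by_frame = largest, mean_largest = mean(largest),
       size_distribution = data.frame(size = as.integer(names(tab)),
                                      count = as.integer(tab)),
       frac_frames_ge = setNames(frac, seq_len(n_sel)))
}
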