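#' Transition-detection configuration
#'
#' Flip-flop events are confirmed by a hysteresis criterion: before and after
#' a transition the molecule's membrane-normal centre-of-mass position must
#' reach a distance `d` from the membrane centre, once with positive and once
#' with negative sign, so that every counted event is a full transfer between
#' leaflets. The default distances are 0.7 nm for species `"A"` and 0.6 nm
#' for species `"B"` (close to each molecule's typical resting distance from
#' the membrane centre); any other species must be configured explicitly.
#'
#' @param thresholds named numeric vector of per-species confirmation
#'   distances d (nm, > 0).
#' @return object of class `transition_config`.
#' @export
transition_config <- function(thresholds = c(A = 0.7, B = 0.6)) {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop_ld("'thresholds' must be a named numeric vector (species -> d)")
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop_ld("all thresholds must be finite and > 0")
  structure(list(thresholds = thresholds), class = "transition_config")
}

.threshold_for <- function(config, species) {
  d <- config$thresholds[species]
  if (is.na(d))
    stop_ld("no transition threshold configured for species '%s'", species)
  as.numeric(d)
}

.one_molecule <- function(ztrace) {
  if (is.numeric(ztrace))
    return(data.frame(time_ns = seq_along(ztrace) - 1, z_nm = ztrace,
                      species = "A", molecule_id = 1L))
  stopifnot(all(c("time_ns", "z_nm") %in% names(ztrace)))
  if (!is.null(ztrace$molecule_id) &&
      length(unique(ztrace$molecule_id)) > 1L)
    stop_ld("z-trace contains multiple molecules; split it first")
  ztrace
}

#' Detect interleaflet flip-flop transitions in a z-trace
#'
#' Implements the hysteresis criterion of [transition_config()]: take the
#' subsequence of samples with `|z| >= d`, map it to signs, and count every
#' sign change as one event. Equivalently: a confirmed-leaflet automaton with
#' dead zone `(-d, d)`. The event timestamp is the first confirming sample in
#' the new leaflet.
#'
#' @param ztrace data frame (`time_ns`, `z_nm`, `species`) for one molecule,
#'   or a bare numeric z vector (species `"A"`).
#' @param config a [transition_config()].
#' @return data frame of events: `time_ns`, `direction` (`"up"` = lower to
#'   upper, `"down"` = upper to lower), `pre_index`, `post_index` (indices of
#'   the confirming excursion samples in the input trace). Zero rows when no
#'   event is confirmed.
#' @export
detect_transitions <- function(ztrace, config = transition_config()) {
  zt <- .one_molecule(ztrace)
  d <- .threshold_for(config, as.character(zt$species[1]))
  z <- zt$z_nm
  empty <- data.frame(time_ns = numeric(0), direction = character(0),
                      pre_index = integer(0), post_index = integer(0))
  if (length(z) < 2L) return(empty)
  idx <- which(abs(z) >= d)
  if (length(idx) < 2L) return(empty)
  s <- ifelse(z[idx] > 0, 1L, -1L)
  ch <- which(diff(s) != 0L)
  if (!length(ch)) return(empty)
  data.frame(time_ns = zt$time_ns[idx[ch + 1L]],
             direction = ifelse(s[ch + 1L] > 0, "up", "down"),
             pre_index = idx[ch], post_index = idx[ch + 1L])
}

#' Replica-averaged transition counts per species
#'
#' Counts flip-flop events per molecule and averages across replicas per
#' species, following the convention of reporting the arithmetic mean of
#' replica counts (which may be fractional, e.g. replicas with 1 and 0 events
#' average to 0.5). Rates are reported per microsecond; when replicas have
#' unequal observation windows, rates are computed per replica and then
#' averaged (a warning is issued).
#'
#' @param ztraces data frame (`time_ns`, `molecule_id`, `species`, `z_nm`)
#'   with an optional `replica` column (default: single replica).
#' @param config a [transition_config()].
#' @return object of class `transition_summary`: list with `per_molecule`
#'   (replica, molecule_id, species, count, observation_ns) and `per_species`
#'   (species, mean_count, rate_per_us, n_traces).
#' @export
summarize_transitions <- function(ztraces, config = transition_config()) {
  if (!nrow(ztraces)) stop_ld("empty z-trace table")
  if (is.null(ztraces$replica)) ztraces$replica <- 1L
  keys <- unique(ztraces[, c("replica", "molecule_id", "species")])
  per <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
    sub <- ztraces[ztraces$replica == keys$replica[k] &
                   ztraces$molecule_id == keys$molecule_id[k], ]
    ev <- detect_transitions(sub, config)
    data.frame(replica = keys$replica[k], molecule_id = keys$molecule_id[k],
               species = keys$species[k], count = nrow(ev),
               observation_ns = max(sub$time_ns) - min(sub$time_ns))
  }))
  if (length(unique(per$observation_ns)) > 1L)
    warning("mixed observation lengths: rates averaged per replica",
            call. = FALSE)
  per$rate_per_us <- per$count / (per$observation_ns / 1000)
  per_species <- do.call(rbind, lapply(split(per, per$species), function(g)
    data.frame(species = g$species[1], mean_count = mean(g$count),
               rate_per_us = mean(g$rate_per_us), n_traces = nrow(g))))
  rownames(per_species) <- NULL
  structure(list(per_molecule = per, per_species = per_species),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("flip-flop transition summary (replica-averaged):\n")
  print(x$per_species, row.names = FALSE)
  invisible(x)
}

#' Per-frame leaflet assignment
#'
#' @param ztrace one-molecule z-trace (see [detect_transitions()]).
#' @param config a [transition_config()] (used by the `confirmed` policy).
#' @param policy `"instantaneous"`: sign of z (`undetermined` only at exactly
#'   0); `"confirmed"`: last leaflet in which `|z| >= d` was reached
#'   (`undetermined` before the first excursion).
#' @return character vector in `upper` / `lower` / `undetermined`.
#' @export
assign_leaflet <- function(ztrace, config = transition_config(),
                           policy = c("instantaneous", "confirmed")) {
  policy <- match.arg(policy)
  zt <- .one_molecule(ztrace)
  z <- zt$z_nm
  if (policy == "instantaneous")
    return(ifelse(z > 0, "upper", ifelse(z < 0, "lower", "undetermined")))
  d <- .threshold_for(config, as.character(zt$species[1]))
  s <- ifelse(abs(z) >= d, sign(z), 0)
  conf <- Reduce(function(prev, cur) if (cur != 0) cur else prev, s,
                 accumulate = TRUE)
  ifelse(conf > 0, "upper", ifelse(conf < 0, "lower", "undetermined"))
}

#' Height distribution of a membrane solute
#'
#' Two representations of the distribution of membrane-normal positions:
#' `full_z` is the plain normalized histogram of z. `intensity_sensitive` is
#' the folded representation used for leaflet-asymmetric statistics: build
#' the full histogram, find whether the higher peak lies at positive or
#' negative z, keep only the samples from that half, and re-histogram them as
#' a function of `|z|`. Exact peak ties go to the positive half (documented
#' tie-break). With `conditioning = "same_leaflet"` only frames where the
#' molecule and its partner occupy the same leaflet (instantaneous sign by
#' default) enter the histogram.
#'
#' @param ztrace one-molecule z-trace or numeric z vector.
#' @param bin_width histogram bin width (nm, default 0.05); bin edges are
#'   aligned so 0 is an edge.
#' @param mode `"full_z"` or `"intensity_sensitive"`.
#' @param conditioning `"none"` or `"same_leaflet"` (requires `partner`).
#' @param partner partner molecule z-trace aligned frame-by-frame with
#'   `ztrace` (same length), used for `same_leaflet` conditioning.
#' @param leaflet_policy leaflet criterion for conditioning, see
#'   [assign_leaflet()].
#' @param config [transition_config()] for the `confirmed` policy.
#' @return object of class `height_histogram`: `breaks`, `mids`, `prob`
#'   (sums to 1), `counts`, `mode`, `conditioning`, `n_samples`, and for the
#'   folded mode `winning_half` (`"positive"`/`"negative"`) and
#'   `winning_share` (that half's probability mass before renormalization).
#' @export
height_histogram <- function(ztrace, bin_width = 0.05,
                             mode = c("full_z", "intensity_sensitive"),
                             conditioning = c("none", "same_leaflet"),
                             partner = NULL,
                             leaflet_policy = "instantaneous",
                             config = transition_config()) {
  mode <- match.arg(mode)
  conditioning <- match.arg(conditioning)
  zt <- .one_molecule(ztrace)
  z <- zt$z_nm
  if (conditioning == "same_leaflet") {
    if (is.null(partner))
      stop_ld("same_leaflet conditioning requires a 'partner' trace")
    pz <- .one_molecule(partner)
    if (nrow(pz) != length(z))
      stop_ld("partner trace length (%d) != trace length (%d)", nrow(pz),
              length(z))
    l1 <- assign_leaflet(zt, config, leaflet_policy)
    l2 <- assign_leaflet(pz, config, leaflet_policy)
    keep <- l1 != "undetermined" & l1 == l2
    z <- z[keep]
    if (!length(z))
      stop_ld("conditioning removed all samples: no same-leaflet frames")
  }
  if (!length(z)) stop_ld("no samples to histogram")
  nb <- max(1L, ceiling(max(abs(z)) / bin_width + 1e-9))
  breaks <- seq(-nb, nb) * bin_width
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = 2L * nb)
  out <- list(mode = mode, conditioning = conditioning, n_samples = length(z),
              bin_width = bin_width)
  if (mode == "full_z") {
    out$breaks <- breaks
    out$mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    out$counts <- counts
    out$prob <- counts / sum(counts)
  } else {
    pos_max <- max(counts[(nb + 1L):(2L * nb)])
    neg_max <- max(counts[1:nb])
    positive_wins <- pos_max >= neg_max  # tie -> positive half
    kept <- if (positive_wins) z[z > 0] else z[z < 0]
    if (!length(kept))
      stop_ld("winning half contains no samples (all z identically 0?)")
    out$winning_half <- if (positive_wins) "positive" else "negative"
    out$winning_share <- length(kept) / length(z)
    fb <- seq(0L, nb) * bin_width
    fc <- tabulate(findInterval(abs(kept), fb, rightmost.closed = TRUE,
                                all.inside = TRUE), nbins = nb)
    out$breaks <- fb
    out$mids <- (fb[-1] + fb[-length(fb)]) / 2
    out$counts <- fc
    out$prob <- fc / sum(fc)
  }
  structure(out, class = "height_histogram")
}

#' @export
print.height_histogram <- function(x, ...) {
  cat(sprintf("height histogram (%s%s): %d samples, %d bins of %.3g nm\n",
              x$mode,
              if (x$conditioning != "none") paste0(", ", x$conditioning) else "",
              x$n_samples, length(x$mids), x$bin_width))
  if (!is.null(x$winning_half))
    cat(sprintf("  folded from the %s half (share %.3f)\n", x$winning_half,
                x$winning_share))
  invisible(x)
}

#' Mode (peak position) of a height histogram
#'
#' @param hist a [height_histogram()] result.
#' @param refine with `refine = TRUE`, the peak position is refined below
#'   the bin width by a three-point parabolic interpolation through the
#'   maximum bin and its neighbours — the standard sub-bin mode estimator,
#'   needed to resolve peak shifts smaller than one bin.
#' @return the z (or |z|) of the distribution peak: the centre of the
#'   highest-probability bin, or its parabolic refinement.
#' @export
histogram_peak <- function(hist, refine = FALSE) {
  stopifnot(inherits(hist, "height_histogram"))
  k <- which.max(hist$prob)
  mid <- hist$mids[k]
  if (!refine || k == 1L || k == length(hist$prob)) return(mid)
  y0 <- hist$prob[k - 1L]; y1 <- hist$prob[k]; y2 <- hist$prob[k + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(mid)
  mid + 0.5 * (y0 - y2) / denom * hist$bin_width
}

#' Orientation profile of a molecular axis across the membrane
#'
#' For each frame, computes the unit vector between two named atoms of a
#' molecule and the angle theta between that axis and the membrane normal
#' (+z), bins the molecule's current centre-of-mass z (relative to the
#' phosphate membrane centre), and reports the mean `|cos(theta)|` per z bin:
#' 1 for an axis along the membrane normal, 0 for an axis lying in the
#' membrane plane.
#'
#' @param traj a [trajectory] object.
#' @param molecule_id molecule whose axis is profiled.
#' @param axis_atoms character 2-vector of atom names defining the axis.
#' @param bin_width z bin width (nm).
#' @param reference_species membrane-centre reference species (default
#'   `"P"`).
#' @return data frame `z_mid`, `mean_abs_cos`, `count` (occupied bins only).
#' @export
orientation_profile <- function(traj, molecule_id, axis_atoms,
                                bin_width = 0.2, reference_species = "P") {
  if (length(axis_atoms) != 2L) stop_ld("axis_atoms must name two atoms")
  i1 <- select_particles(traj, molecule_id = molecule_id,
                         atom_name = axis_atoms[1])
  i2 <- select_particles(traj, molecule_id = molecule_id,
                         atom_name = axis_atoms[2])
  if (length(i1) != 1L || length(i2) != 1L)
    stop_ld("axis atoms must resolve to exactly one particle each")
  mol <- select_particles(traj, molecule_id = molecule_id)
  ref <- select_particles(traj, species = reference_species)
  if (!length(ref))
    stop_ld("reference species '%s' absent from topology", reference_species)
  nf <- n_frames(traj)
  zc <- numeric(nf); ac <- numeric(nf)
  for (f in seq_len(nf)) {
    v <- traj$coords[i2, , f] - traj$coords[i1, , f]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) stop_ld("degenerate axis (coincident atoms) at frame %d", f)
    ac[f] <- abs(v[3] / nv)
    zc[f] <- compute_com(traj, f, mol)[3] - compute_com(traj, f, ref)[3]
  }
  bin <- floor(zc / bin_width)
  agg <- tapply(ac, bin, mean)
  cnt <- tapply(ac, bin, length)
  data.frame(z_mid = (as.numeric(names(agg)) + 0.5) * bin_width,
             mean_abs_cos = as.numeric(agg), count = as.integer(cnt))
}
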