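# Independent oracles and fixture builders used across the suite.

# Brute-force flip-flop oracle: a dead-zone automaton walked sample by
# sample, coded independently of detect_transitions().
oracle_transitions <- function(z, d) {
  last <- 0L
  idx <- integer(0)
  dirs <- integer(0)
  for (k in seq_along(z)) {
    if (abs(z[k]) >= d) {
      s <- if (z[k] > 0) 1L else -1L
      if (last != 0L && s != last) {
        idx <- c(idx, k)
        dirs <- c(dirs, s)
      }
      last <- s
    }
  }
  list(index = idx, dir = dirs)
}

# Independent fold-and-filter oracle for the intensity-sensitive histogram
# (uses hist(); valid for continuous samples where edge ties have measure 0).
oracle_fold_histogram <- function(z, bw) {
  nb <- max(1L, ceiling(max(abs(z)) / bw + 1e-9))
  br <- seq(-nb, nb) * bw
  counts <- hist(z, breaks = br, plot = FALSE)$counts
  pos <- counts[(nb + 1L):(2L * nb)]
  neg <- counts[1:nb]
  keep <- if (max(pos) >= max(neg)) z[z > 0] else z[z < 0]
  fb <- seq(0L, nb) * bw
  fc <- hist(abs(keep), breaks = fb, plot = FALSE)$counts
  fc / sum(fc)
}

# O(N^2) union-find clustering oracle on a precomputed distance matrix.
oracle_clusters <- function(dmat, cutoff) {
  n <- nrow(dmat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (dmat[i, j] <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# are two labelings the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}

# minimum-image distance matrix, coded independently of the package
oracle_dist <- function(xyz, box, lateral = TRUE) {
  n <- nrow(xyz)
  d <- matrix(0, n, n)
  dims <- if (lateral) 1:2 else 1:3
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in dims) {
        dd <- xyz[i, k] - xyz[j, k]
        dd <- dd - box[k] * round(dd / box[k])
        s <- s + dd^2
      }
      d[i, j] <- sqrt(s)
    }
  }
  d
}

# numeric CDF of the double-well stationary density exp(-U(z))
stationary_cdf <- function(barrier, z0 = 1, lim = 3) {
  zs <- seq(-lim, lim, by = 0.001)
  w <- exp(-barrier * ((zs / z0)^2 - 1)^2)
  cdf <- cumsum(w) / sum(w)
  function(q) approx(zs, cdf, xout = q, rule = 2)$y
}

# build a small trajectory from a list of n x 3 frame matrices
make_traj <- function(frames, box = c(10, 10, 10), species = NULL,
                      molecule_id = NULL, atom_name = NULL, mass = NULL,
                      times = NULL) {
  n <- nrow(frames[[1]])
  coords <- array(unlist(frames), dim = c(n, 3L, length(frames)))
  trajectory(
    times = times %||% (seq_along(frames) - 1),
    coords = coords, box = box,
    topology = data.frame(
      molecule_id = molecule_id %||% seq_len(n),
      species = species %||% rep("A", n),
      atom_name = atom_name %||% rep("COM", n),
      mass = mass %||% rep(1, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zdf <- function(z, species = "A", times = NULL) {
  data.frame(time_ns = times %||% (seq_along(z) - 1), molecule_id = 1L,
             species = species, z_nm = z)
}

random_ztrace <- function(len, scale = 1) {
  # mix of white noise and a random walk so both leaflets get visited
  cumsum(rnorm(len, 0, 0.2 * scale)) * 0.3 + rnorm(len, 0, scale)
}
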