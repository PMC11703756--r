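#' Simulate per-GUV fluorescence traces for transport assays
#'
#' Emulates Rhod2-type readouts of ionophore-mediated metal transport into
#' giant unilamellar vesicles: each GUV holds a constant baseline intensity
#' until the ionophore addition time, then relaxes mono-exponentially to a
#' plateau. In `quench` mode (Ni2+/Cu2+ quenching the Ca2+-Rhod2 complex)
#' the plateau is `I0 * (1 - fraction)`; in `gain` mode (Ca2+ turning Rhod2
#' on) it is `I0 * (1 + fraction)`. Gaussian noise is added pointwise and
#' the true transport fraction per GUV is returned as ground truth.
#'
#' @param n_guvs number of GUVs (>= 1).
#' @param direction `"quench"` or `"gain"`.
#' @param transport_fraction true per-GUV transported fraction in `[0, 1]`
#'   (recycled); default: drawn uniformly on `[0, 1]`.
#' @param rate_per_min mono-exponential rate constant(s) (1/min, >= 0;
#'   recycled). A rate of 0 leaves the trace at baseline.
#' @param i0 common baseline intensity (a.u.).
#' @param noise_sd Gaussian noise sd (a.u., >= 0).
#' @param addition_time_min ionophore addition time (min, inside the window).
#' @param duration_min,dt_min trace window and sampling interval (min).
#' @param seed integer seed.
#' @return list: `traces` (data frame `time_min`, `guv_id`, `channel`,
#'   `intensity`), `truth` (data frame `guv_id`, `transport_fraction`,
#'   `rate_per_min`), `addition_time_min`, `direction`, `i0`.
#' @export
simulate_fluorescence_traces <- function(n_guvs,
                                         direction = c("quench", "gain"),
                                         transport_fraction = NULL,
                                         rate_per_min = 0.5, i0 = 100,
                                         noise_sd = 0,
                                         addition_time_min = 10,
                                         duration_min = 40, dt_min = 0.5,
                                         seed = 1L) {
  direction <- match.arg(direction)
  if (n_guvs < 1L) stop_ld("n_guvs must be >= 1")
  if (noise_sd < 0) stop_ld("noise sd must be >= 0")
  if (any(rate_per_min < 0)) stop_ld("rates must be >= 0")
  if (addition_time_min <= 0 || addition_time_min >= duration_min)
    stop_ld("addition time must lie inside the trace window")
  set.seed(as.integer(seed))
  frac <- rep_len(transport_fraction %||% runif(n_guvs), n_guvs)
  rate <- rep_len(rate_per_min, n_guvs)
  times <- seq(0, duration_min, by = dt_min)
  sgn <- if (direction == "quench") -1 else 1
  traces <- do.call(rbind, lapply(seq_len(n_guvs), function(g) {
    plateau <- i0 * (1 + sgn * frac[g])
    dt_rel <- pmax(times - addition_time_min, 0)
    ideal <- ifelse(times < addition_time_min, i0,
                    plateau + (i0 - plateau) * exp(-rate[g] * dt_rel))
    if (rate[g] == 0) ideal <- rep(i0, length(times))
    data.frame(time_min = times, guv_id = g, channel = "Rhod2",
               intensity = pmax(ideal + rnorm(length(times), 0, noise_sd), 0))
  }))
  list(traces = traces,
       truth = data.frame(guv_id = seq_len(n_guvs),
                          transport_fraction = frac, rate_per_min = rate),
       addition_time_min = addition_time_min, direction = direction, i0 = i0)
}

#' Simulate GUV area traces with and without lysis
#'
#' Non-lysing GUVs fluctuate around their initial area; lysing GUVs collapse
#' exponentially towards zero after a lysis onset time (the vesicle breaking
#' up into micelles).
#'
#' @param n number of GUVs (>= 1).
#' @param lysing logical vector (recycled) marking which GUVs lyse.
#' @param initial_area_um2 starting area (um^2).
#' @param onset_min lysis onset time (min).
#' @param collapse_rate_per_min exponential collapse rate after onset.
#' @param noise_frac Gaussian noise sd as a fraction of the initial area.
#' @param duration_min,dt_min window and sampling interval (min).
#' @param seed integer seed.
#' @return list: `traces` (data frame `time_min`, `guv_id`, `area_um2`),
#'   `truth` (data frame `guv_id`, `lysing`, `onset_min`).
#' @export
simulate_area_traces <- function(n, lysing = FALSE,
                                 initial_area_um2 = 300, onset_min = 10,
                                 collapse_rate_per_min = 1.5,
                                 noise_frac = 0.02, duration_min = 30,
                                 dt_min = 0.5, seed = 1L) {
  if (n < 1L) stop_ld("n must be >= 1")
  if (noise_frac < 0) stop_ld("noise fraction must be >= 0")
  set.seed(as.integer(seed))
  lysing <- rep_len(lysing, n)
  times <- seq(0, duration_min, by = dt_min)
  traces <- do.call(rbind, lapply(seq_len(n), function(g) {
    ideal <- if (lysing[g]) {
      ifelse(times < onset_min, initial_area_um2,
             initial_area_um2 * exp(-collapse_rate_per_min *
                                    (times - onset_min)))
    } else rep(initial_area_um2, length(times))
    area <- pmax(ideal + rnorm(length(times), 0,
                               noise_frac * initial_area_um2), 0)
    data.frame(time_min = times, guv_id = g, area_um2 = area)
  }))
  list(traces = traces,
       truth = data.frame(guv_id = seq_len(n), lysing = lysing,
                          onset_min = ifelse(lysing, onset_min, NA_real_)))
}

#' Simulate sensor readouts around the differentiation fate centroids
#'
#' Draws synthetic per-GUV end-point readouts (urease-sensor fold change,
#' galactose-oxidase-sensor fold change, dye leakage at 20 min, lysis flag)
#' scattered around qualitative centroids of the five terminal fates, for
#' exercising [classify_from_readouts()].
#'
#' @param n_per_fate GUVs per fate.
#' @param noise_sd sd of the Gaussian scatter on the fold channels
#'   (leakage scatter is `10 * noise_sd` percentage points).
#' @param seed integer seed.
#' @return data frame: `true_fate`, `urease_fold`, `gaoa_fold`,
#'   `leakage_pct`, `lysed`.
#' @export
simulate_fate_readouts <- function(n_per_fate = 10L, noise_sd = 0.3,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  centroids <- data.frame(
    fate = c("A-b", "A-c", "B-a", "B-c", "C"),
    urease = c(5, 5, 1, 1, 0.5),
    gaoa = c(1.4, 1, 5, 5, 0.5),
    leakage = c(5, 40, 5, 40, 0),
    lysed = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  do.call(rbind, lapply(seq_len(nrow(centroids)), function(i) {
    cen <- centroids[i, ]
    data.frame(
      true_fate = cen$fate,
      urease_fold = pmax(rnorm(n_per_fate, cen$urease, noise_sd), 0),
      gaoa_fold = pmax(rnorm(n_per_fate, cen$gaoa, noise_sd), 0),
      leakage_pct = pmin(pmax(rnorm(n_per_fate, cen$leakage,
                                    10 * noise_sd), -5), 105),
      lysed = cen$lysed)
  }))
}
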