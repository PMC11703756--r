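#' Per-GUV transport percentage from a quench trace
#'
#' Quantifies metal transport into a Rhod2-loaded GUV from the quenching of
#' its fluorescence:
#' \deqn{\%\,transport = (I_{initial} - I_{final}) / I_{mean} \times 100}
#' where `I_initial` and `I_final` are the GUV's intensity before and after
#' ionophore addition and `I_mean` is the initial mean intensity of all GUVs
#' analysed in the sample. `I_initial` is averaged over the last
#' `pre_window` samples before the addition and `I_final` over the last
#' `post_window` samples of the trace (single-snapshot behaviour with
#' window 1). Negative values are reported, not clipped; a QC flag marks
#' magnitudes above 105.
#'
#' @param trace data frame `time_min`, `intensity` for one GUV.
#' @param i_mean sample-wide initial mean intensity (a.u., > 0).
#' @param addition_time_min ionophore addition time (must lie inside the
#'   trace so both windows exist).
#' @param pre_window,post_window window sizes in samples (default 3).
#' @return numeric percentage with attribute `qc` (`"ok"` or
#'   `"out_of_range"`).
#' @export
percent_transport_quench <- function(trace, i_mean, addition_time_min,
                                     pre_window = 3L, post_window = 3L) {
  if (is.null(addition_time_min) || is.na(addition_time_min))
    stop_ld("missing ionophore addition event")
  if (!is.finite(i_mean) || i_mean <= 0) stop_ld("I_mean must be > 0")
  pre <- trace$intensity[trace$time_min < addition_time_min]
  post <- trace$intensity[trace$time_min >= addition_time_min]
  if (!length(pre) || !length(post))
    stop_ld("trace needs samples both before and after the addition event")
  i_initial <- mean(utils::tail(pre, pre_window))
  i_final <- mean(utils::tail(post, post_window))
  out <- (i_initial - i_final) / i_mean * 100
  attr(out, "qc") <- if (abs(out) > 105) "out_of_range" else "ok"
  out
}

#' Per-GUV relative transport percentage for Ca2+ (gain mode)
#'
#' Ca2+ entry turns Rhod2 fluorescent, so transport is expressed relative to
#' the mean intensity change of the reference condition (the Ca2+-selective
#' ionophore with Ca2+ present), which defines 100 %:
#' \deqn{\%\,relative\,transport = (I_{final} - I_{initial}) /
#'   \overline{\Delta I}_{ref} \times 100}
#'
#' @param trace data frame `time_min`, `intensity` for one GUV.
#' @param delta_i_ref mean `I_final - I_initial` of the reference-condition
#'   GUV set (a.u., non-zero). See [reference_delta_i()].
#' @param addition_time_min ionophore addition time.
#' @param pre_window,post_window window sizes in samples.
#' @return numeric percentage.
#' @export
percent_relative_transport_ca <- function(trace, delta_i_ref,
                                          addition_time_min,
                                          pre_window = 3L, post_window = 3L) {
  if (!is.finite(delta_i_ref) || delta_i_ref == 0)
    stop_ld("reference mean intensity change must be non-zero")
  if (is.null(addition_time_min) || is.na(addition_time_min))
    stop_ld("missing ionophore addition event")
  pre <- trace$intensity[trace$time_min < addition_time_min]
  post <- trace$intensity[trace$time_min >= addition_time_min]
  if (!length(pre) || !length(post))
    stop_ld("trace needs samples both before and after the addition event")
  i_initial <- mean(utils::tail(pre, pre_window))
  i_final <- mean(utils::tail(post, post_window))
  (i_final - i_initial) / delta_i_ref * 100
}

#' Reference-condition mean intensity change
#'
#' Computes the mean `I_final - I_initial` over a set of reference GUV
#' traces, the normalizer of [percent_relative_transport_ca()].
#'
#' @param traces data frame `time_min`, `guv_id`, `intensity`.
#' @param addition_time_min ionophore addition time.
#' @param pre_window,post_window window sizes in samples.
#' @return mean intensity change (a.u.).
#' @export
reference_delta_i <- function(traces, addition_time_min, pre_window = 3L,
                              post_window = 3L) {
  deltas <- vapply(split(traces, traces$guv_id), function(tr) {
    pre <- tr$intensity[tr$time_min < addition_time_min]
    post <- tr$intensity[tr$time_min >= addition_time_min]
    mean(utils::tail(post, post_window)) - mean(utils::tail(pre, pre_window))
  }, numeric(1))
  mean(deltas)
}

#' Plate-reader transport percentage time series
#'
#' Normalizes a plate-reader well series to the extreme intensities observed
#' within one experiment set:
#' quench: \deqn{\% = (I_{initial} - I_x)/(I_{initial} - I_{min}) \times 100}
#' gain:   \deqn{\% = (I_x - I_{initial})/(I_{max} - I_{initial}) \times 100}
#' where `I_x` is the intensity at each timepoint. Values are reported
#' unclipped; a QC flag marks any excursion outside `[-5, 105]` (noise
#' tolerance).
#'
#' @param series data frame `time_min`, `intensity` for one well.
#' @param direction `"quench"` or `"gain"`.
#' @param i_initial intensity at time zero (default: first sample).
#' @param i_min,i_max extreme intensities within the experiment set
#'   (quench needs `i_min`, gain needs `i_max`).
#' @return data frame `time_min`, `percent` with attribute `qc`.
#' @export
platereader_percent_transport <- function(series,
                                          direction = c("quench", "gain"),
                                          i_initial = NULL, i_min = NULL,
                                          i_max = NULL) {
  direction <- match.arg(direction)
  i_initial <- i_initial %||% series$intensity[1]
  pct <- if (direction == "quench") {
    if (is.null(i_min)) stop_ld("quench normalization requires i_min")
    if (i_initial == i_min)
      stop_ld("degenerate normalizer: I_initial == I_min")
    (i_initial - series$intensity) / (i_initial - i_min) * 100
  } else {
    if (is.null(i_max)) stop_ld("gain normalization requires i_max")
    if (i_max == i_initial)
      stop_ld("degenerate normalizer: I_max == I_initial")
    (series$intensity - i_initial) / (i_max - i_initial) * 100
  }
  out <- data.frame(time_min = series$time_min, percent = pct)
  attr(out, "qc") <- if (any(pct < -5 | pct > 105)) "out_of_range" else "ok"
  out
}

#' Dye retention percentage at fixed timepoints
#'
#' Retention of an encapsulated membrane-impermeable dye (sulfo-Cy5) as a
#' percentage of the intensity at time zero, which defines the 100 %
#' baseline: `I_t / I_0 * 100`, evaluated by nearest-sample lookup at the
#' requested timepoints. 100 minus the result is the leaked percentage.
#'
#' @param trace data frame `time_min`, `intensity` for one GUV.
#' @param timepoints_min requested timepoints (min), default 20/40/60.
#' @param tol_min nearest-sample tolerance (min).
#' @return named numeric vector of percentages (names = timepoints).
#' @export
leakage_percent <- function(trace, timepoints_min = c(20, 40, 60),
                            tol_min = 1) {
  i0_idx <- which.min(abs(trace$time_min))
  i0 <- trace$intensity[i0_idx]
  if (!is.finite(i0) || i0 <= 0) stop_ld("intensity at t = 0 must be > 0")
  out <- vapply(timepoints_min, function(tp) {
    k <- which.min(abs(trace$time_min - tp))
    if (abs(trace$time_min[k] - tp) > tol_min)
      stop_ld("no sample within %.2g min of requested timepoint %.4g", tol_min,
              tp)
    trace$intensity[k] / i0 * 100
  }, numeric(1))
  setNames(out, timepoints_min)
}

#' Detect GUV lysis from an area time series
#'
#' A GUV is called lysed when its median-smoothed area falls below
#' `threshold_fraction` of the initial area and stays below for the rest of
#' the trace; the onset is the first such time. A 3-point running median
#' suppresses single-sample noise.
#'
#' @param area_trace data frame `time_min`, `area_um2` for one GUV
#'   (>= 2 samples).
#' @param threshold_fraction lysis threshold as a fraction of the initial
#'   area (default 0.5).
#' @return list: `lysed` (logical), `onset_min` (`NA` when not lysed).
#' @export
detect_lysis <- function(area_trace, threshold_fraction = 0.5) {
  a <- area_trace$area_um2
  if (length(a) < 2L) stop_ld("need at least 2 area samples")
  sm <- if (length(a) >= 3L) stats::runmed(a, 3L) else a
  thr <- threshold_fraction * sm[1]
  below <- sm < thr
  stays <- rev(cumprod(rev(below))) > 0  # below from here to the end
  if (!any(stays)) return(list(lysed = FALSE, onset_min = NA_real_))
  list(lysed = TRUE, onset_min = area_trace$time_min[which(stays)[1]])
}
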