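# Optical / intracellular action-potential trace analysis: ratiometric trace
# construction, AP detection, APD at a repolarization level with Bazett rate
# correction, AP averaging, per-cell summaries, field-potential-duration
# correction, and patch-clamp IV-curve assembly with leak and drug
# subtraction.

#' Build a ratiometric trace from two fluorescence channels
#'
#' Pointwise numerator / denominator ratio (e.g. the long- over
#' short-wavelength emission of a voltage-sensitive dye). Samples where the
#' denominator is not positive are set to NA and counted in
#' `attr(, "n_flagged")`.
#'
#' @param numerator,denominator equal-length channel vectors
#' @param time time stamps in ms, uniformly sampled, strictly increasing
#' @param metadata optional list (channel labels etc.)
#' @return object of class `ratio_trace`: list(time, signal,
#'   sampling_interval, metadata)
#' @export
ratio_trace <- function(numerator, denominator, time, metadata = list()) {
  stopifnot(length(numerator) == length(denominator),
            length(numerator) == length(time))
  as_trace(time, ifelse(denominator > 0, numerator / denominator, NA_real_),
           metadata = c(metadata, list(ratio = TRUE)),
           n_flagged = sum(denominator <= 0))
}

# Internal constructor shared by ratio_trace and the generators; also
# accepts membrane-potential traces (mV) directly.
as_trace <- function(time, signal, metadata = list(), n_flagged = 0L) {
  stopifnot(length(time) == length(signal), length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  si <- median(dt)
  if (max(abs(dt - si)) > 0.01 * si)
    warning("sampling jitter exceeds 1% of the sampling interval")
  if (n_flagged > 0L)
    warning(n_flagged, " sample(s) with non-positive denominator set to NA")
  structure(list(time = time, signal = signal, sampling_interval = si,
                 metadata = metadata, n_flagged = n_flagged),
            class = "ratio_trace")
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples, %.3g ms interval, %.3g s long\n",
              length(x$time), x$sampling_interval,
              diff(range(x$time)) / 1000))
  invisible(x)
}

#' Analysis configuration for AP traces
#'
#' @param min_rr_ms minimum inter-AP interval accepted by the detector
#' @param smooth_ms width of the moving-average window applied to the
#'   signal for baseline/amplitude estimation and falling-limb crossings
#'   (the rising limb uses raw samples for sub-sample onset precision)
#' @param deriv_threshold_frac upstroke threshold as a fraction of the
#'   maximal derivative
#' @param noise_mult multiple of the derivative MAD a candidate upstroke
#'   must exceed (rejects flat, noise-only traces)
#' @param baseline_quantile quantile of the preceding diastolic segment
#'   used as the per-AP baseline (robust to photobleaching drift)
#' @param onset_frac fraction of the amplitude above baseline defining the
#'   AP takeoff point
#' @return list of class `ap_config`
#' @export
ap_config <- function(min_rr_ms = 250, smooth_ms = 20,
                      deriv_threshold_frac = 0.5, noise_mult = 8,
                      baseline_quantile = 0.10, onset_frac = 0.10) {
  structure(list(min_rr_ms = min_rr_ms, smooth_ms = smooth_ms,
                 deriv_threshold_frac = deriv_threshold_frac,
                 noise_mult = noise_mult,
                 baseline_quantile = baseline_quantile,
                 onset_frac = onset_frac), class = "ap_config")
}

#' Detect action-potential upstrokes
#'
#' Returns one sample index per AP, at the maximal-derivative point of each
#' upstroke. The signal is smoothed before differentiation (implicit
#' detrending: a linear drift contributes a constant to the derivative and
#' is removed with the noise floor by the MAD gate), candidate runs above
#' threshold are collapsed to their derivative maximum, and detections
#' closer than `min_rr_ms` keep only the steeper one. Flat or noise-only
#' traces yield an empty result.
#'
#' @param trace a `ratio_trace` (or membrane-potential trace)
#' @param config an `ap_config`
#' @return integer vector of upstroke sample indices (possibly empty)
#' @export
detect_aps <- function(trace, config = ap_config()) {
  stopifnot(inherits(trace, "ratio_trace"))
  x <- trace$signal
  if (anyNA(x)) x <- approx_na(x)
  dt <- trace$sampling_interval
  if (length(x) * dt < 1000) stop("need at least 1 s of signal")
  xs <- moving_avg(x, round(config$smooth_ms / dt))
  d <- diff(xs) / dt
  d <- d - median(d)          # remove constant drift slope
  dmax <- max(d)
  noise <- mad(d)
  if (dmax <= 0 || (noise > 0 && dmax < config$noise_mult * noise))
    return(integer(0))
  thr <- config$deriv_threshold_frac * dmax
  above <- d > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  idx <- vapply(runs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(d[seg])]
  }, integer(1))
  # refine each detection on the raw derivative: smoothing flattens the
  # upstroke derivative over the window, so the smoothed argmax can sit up
  # to half a window early
  draw <- diff(x) / dt
  half <- max(1L, round(config$smooth_ms / dt / 2) + 1L)
  idx <- vapply(idx, function(j) {
    seg <- max(1L, j - half):min(length(draw), j + half)
    seg[which.max(draw[seg])]
  }, integer(1))
  d <- draw
  # enforce minimum separation, keeping the steeper detection
  min_sep <- config$min_rr_ms / dt
  idx <- idx[order(idx)]
  keep <- rep(TRUE, length(idx))
  last <- 1L
  for (i in seq_along(idx)[-1L]) {
    if (idx[i] - idx[last] < min_sep) {
      if (d[idx[i]] > d[idx[last]]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  idx[keep]
}

# Linear interpolation over interior NAs (flagged ratio samples).
approx_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("trace is almost entirely NA")
  stats::approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
}

# Per-AP feature extraction. Returns a data.frame with one row per detected
# upstroke; APs whose repolarization does not complete before the next AP or
# the end of the trace are marked invalid.
.ap_features <- function(trace, ups, level = 0.9, config = ap_config()) {
  x <- approx_na(trace$signal)
  t <- trace$time
  dt <- trace$sampling_interval
  xs <- moving_avg(x, round(config$smooth_ms / dt))
  n <- length(x)
  res <- lapply(seq_along(ups), function(i) {
    up <- ups[i]
    prev <- if (i > 1L) ups[i - 1L] else NA_integer_
    nxt <- if (i < length(ups)) ups[i + 1L] else NA_integer_
    lo <- if (is.na(prev)) 1L else prev
    hi <- if (is.na(nxt)) n else nxt - 1L
    # diastolic segment: latter half of the preceding inter-AP gap
    dia <- if (is.na(prev)) lo:max(lo, up - 2L)
           else max(prev + (up - prev) %/% 2L, prev + 1L):max(up - 2L, prev + 1L)
    baseline <- unname(quantile(xs[dia], config$baseline_quantile, names = FALSE))
    peak <- max(xs[up:hi])
    amp <- peak - baseline
    bad <- function() data.frame(upstroke_time = t[up], baseline = baseline,
                                 amplitude = amp, peak_value = peak,
                                 apd = NA_real_, rr = NA_real_,
                                 capd = NA_real_, valid = FALSE)
    if (!is.finite(amp) || amp <= 0) return(bad())
    # onset: last raw sample at/below baseline + onset_frac * amplitude
    L0 <- baseline + config$onset_frac * amp
    j <- up
    while (j <= hi && x[j] <= L0) j <- j + 1L   # in case max-derivative sits low
    while (j > lo && x[j - 1L] > L0) j <- j - 1L
    if (j <= lo || j > hi) return(bad())
    fr <- (L0 - x[j - 1L]) / (x[j] - x[j - 1L])
    fr <- min(max(fr, 0), 1)
    onset_t <- t[j - 1L] + fr * dt
    # falling-limb crossing of baseline + (1 - level) * amplitude, on the
    # smoothed signal, searched from the smoothed peak forward
    L <- baseline + (1 - level) * amp
    pk <- up - 1L + which.max(xs[up:hi])
    seg <- pk:hi
    below <- which(xs[seg] <= L)
    if (!length(below)) return(bad())     # repolarization incomplete
    k <- seg[below[1L]]
    if (k == pk) return(bad())
    fr2 <- (xs[k - 1L] - L) / (xs[k - 1L] - xs[k])
    cross_t <- t[k - 1L] + fr2 * dt
    rr <- if (is.na(prev)) NA_real_ else t[up] - t[prev]
    apd <- cross_t - onset_t
    data.frame(upstroke_time = t[up], baseline = baseline, amplitude = amp,
               peak_value = peak, apd = apd, rr = rr,
               capd = if (is.na(rr)) NA_real_ else bazett_correct(apd, rr),
               valid = apd > 0)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(upstroke_time = numeric(0), baseline = numeric(0),
                      amplitude = numeric(0), peak_value = numeric(0),
                      apd = numeric(0), rr = numeric(0), capd = numeric(0),
                      valid = logical(0))
  out
}

#' Action-potential duration at a repolarization level
#'
#' Time from the AP takeoff point (last crossing of baseline + 10% of
#' amplitude before the upstroke, interpolated between raw samples) to the
#' linearly interpolated crossing of baseline + (1 - level) x amplitude on
#' the falling limb. `level = 0.9` gives the APD90. The measure is
#' invariant under positive affine transforms of the signal, since both
#' thresholds are defined relative to the per-AP baseline and amplitude.
#'
#' @param trace a `ratio_trace`
#' @param upstroke_index sample index from [detect_aps()]
#' @param level repolarization fraction (0.9 = APD90)
#' @param config an `ap_config`
#' @return duration in ms, or NA if repolarization does not complete within
#'   the trace (the AP is invalid)
#' @export
apd_at_level <- function(trace, upstroke_index, level = 0.9,
                         config = ap_config()) {
  ups <- detect_aps(trace, config)
  tol <- config$min_rr_ms / trace$sampling_interval / 2
  if (length(ups) && min(abs(ups - upstroke_index)) <= tol) {
    upstroke_index <- ups[which.min(abs(ups - upstroke_index))]
  } else {
    ups <- sort(unique(c(ups, upstroke_index)))
  }
  f <- .ap_features(trace, ups, level = level, config = config)
  f$apd[which(ups == upstroke_index)]
}

#' Bazett rate correction
#'
#' Divides a duration by the square root of the preceding cycle length in
#' seconds, removing the first-order dependence of repolarization time on
#' beat rate: corrected = duration / sqrt(rr / 1000). Identity at
#' rr = 1000 ms; monotone decreasing in rr.
#'
#' @param duration duration in ms (APD, FPD, QT)
#' @param rr preceding inter-beat interval in ms (> 0)
#' @return corrected duration in ms
#' @examples
#' bazett_correct(400, 640)  # 500
#' @export
bazett_correct <- function(duration, rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be positive")
  duration / sqrt(rr / 1000)
}

#' Rate-corrected field-potential duration
#'
#' Applies the Bazett correction to a field-potential duration measured on
#' a multielectrode array: cFPD = FPD / sqrt(beat_interval / 1000). FPD and
#' beat interval are taken as provided (typically read out by the MEA
#' vendor software); see [fpd_extract()] for a best-effort extractor.
#'
#' @param fpd field-potential duration in ms
#' @param beat_interval inter-beat interval in ms
#' @return cFPD in ms
#' @export
cfpd <- function(fpd, beat_interval) {
  if (any(fpd <= 0)) stop("fpd must be positive")
  bazett_correct(fpd, beat_interval)
}

#' Upstroke-aligned average AP waveform
#'
#' Averages `n` consecutive AP windows aligned on their upstrokes; the
#' window length is the median inter-upstroke interval. If fewer than `n`
#' APs are available all are used, with a warning.
#'
#' @param trace a `ratio_trace`
#' @param upstroke_indices indices from [detect_aps()]
#' @param n number of APs to average
#' @param pre_ms time included before the upstroke
#' @return list(time, signal, n_averaged) with time relative to upstroke
#' @export
average_ap <- function(trace, upstroke_indices, n = 15L, pre_ms = 100) {
  if (length(upstroke_indices) < 2L) stop("need at least 2 detected APs")
  if (length(upstroke_indices) < n) {
    warning("only ", length(upstroke_indices), " APs available; averaging all")
    n <- length(upstroke_indices)
  }
  ups <- upstroke_indices[seq_len(n)]
  dt <- trace$sampling_interval
  rr <- median(diff(upstroke_indices)) * dt
  pre <- round(pre_ms / dt)
  len <- round(rr / dt)
  x <- approx_na(trace$signal)
  wins <- lapply(ups, function(u) {
    i0 <- u - pre
    i1 <- u + len
    if (i0 < 1L || i1 > length(x)) return(NULL)
    x[i0:i1]
  })
  wins <- Filter(Negate(is.null), wins)
  if (length(wins) < 2L) stop("fewer than 2 complete AP windows")
  m <- colMeans(do.call(rbind, wins))
  list(time = (seq_along(m) - 1L - pre) * dt, signal = m,
       n_averaged = length(wins))
}

#' Per-cell AP summary
#'
#' Detects APs, extracts per-AP features and reports per-cell medians of
#' APD90, RR and Bazett-corrected APD90. The first AP of a trace has no
#' preceding cycle and is excluded from the rate-corrected statistics.
#' Cells with fewer than `min_valid` valid APs are flagged and carry NA
#' summaries.
#'
#' @param trace a `ratio_trace`
#' @param config an `ap_config`
#' @param level repolarization fraction
#' @param min_valid minimum number of valid APs for a summary
#' @return object of class `ap_summary`: list(n_aps, n_valid, n_invalid,
#'   median_apd90, median_rr, median_capd90, flagged, features)
#' @export
analyze_cell <- function(trace, config = ap_config(), level = 0.9,
                         min_valid = 3L) {
  ups <- detect_aps(trace, config)
  f <- if (length(ups)) .ap_features(trace, ups, level = level, config = config)
       else .ap_features(trace, integer(0), level = level, config = config)
  v <- f[f$valid, , drop = FALSE]
  flagged <- nrow(v) < min_valid
  structure(list(
    n_aps = nrow(f), n_valid = nrow(v), n_invalid = nrow(f) - nrow(v),
    median_apd90 = if (flagged) NA_real_ else median(v$apd),
    median_rr = if (flagged) NA_real_ else median(v$rr, na.rm = TRUE),
    median_capd90 = if (flagged) NA_real_ else median(v$capd, na.rm = TRUE),
    flagged = flagged, level = level, features = f), class = "ap_summary")
}

#' @export
print.ap_summary <- function(x, ...) {
  cat(sprintf("AP summary: %d APs (%d valid)%s\n", x$n_aps, x$n_valid,
              if (x$flagged) " -- FLAGGED (too few valid APs)" else ""))
  if (!x$flagged)
    cat(sprintf("  median APD%.0f = %.1f ms, RR = %.0f ms, cAPD%.0f = %.1f ms\n",
                100 * x$level, x$median_apd90, x$median_rr,
                100 * x$level, x$median_capd90))
  invisible(x)
}

#' Best-effort field-potential duration extractor
#'
#' Heuristic utility, clearly flagged as such: vendor software normally
#' reads the FPD. Takes the sharp depolarization spike as the global
#' extremum of the detrended signal and the repolarization wave as the
#' largest detrended excursion in the search window after it; FPD is the
#' spike-to-repolarization-peak time.
#'
#' @param trace a `ratio_trace` holding one beat of field potential
#' @param blank_ms dead time after the spike excluded from the search
#' @param search_ms length of the repolarization search window
#' @return list(fpd, spike_time, repol_time)
#' @export
fpd_extract <- function(trace, blank_ms = 80, search_ms = 600) {
  x <- approx_na(trace$signal)
  t <- trace$time
  xd <- x - median(x)
  spike <- which.max(abs(xd))
  dt <- trace$sampling_interval
  from <- spike + round(blank_ms / dt)
  to <- min(length(x), spike + round(search_ms / dt))
  if (from >= to) stop("trace too short after the spike")
  rep_i <- from - 1L + which.max(abs(xd[from:to]))
  list(fpd = t[rep_i] - t[spike], spike_time = t[spike], repol_time = t[rep_i])
}

# ---- patch-clamp IV analysis ----------------------------------------------

#' Assemble an IV curve from voltage-step current records
#'
#' For each depolarizing step, extracts either the signed peak current
#' (largest absolute excursion, e.g. the L-type calcium current) or the mean
#' current over a terminal window of the step (steady-state, e.g. slow
#' delayed-rectifier tails), and normalizes to the cell capacitance to give
#' current density in pA/pF.
#'
#' @param step_records list of `list(v = test potential mV, i = current pA
#'   vector)` entries
#' @param capacitance cell capacitance in pF (> 0)
#' @param mode `"peak"` or `"end"`
#' @param end_fraction fraction of the step length defining the terminal
#'   window in `"end"` mode
#' @return data.frame of class `iv_curve` with columns test_potential and
#'   current_density, sorted by potential; capacitance and mode as attributes
#' @export
iv_curve <- function(step_records, capacitance, mode = c("peak", "end"),
                     end_fraction = 0.1) {
  mode <- match.arg(mode)
  stopifnot_scalar_num(capacitance, "capacitance", positive = TRUE)
  v <- vapply(step_records, function(s) s$v, numeric(1))
  if (anyDuplicated(v)) stop("test potentials must be unique")
  val <- vapply(step_records, function(s) {
    i <- s$i
    if (!length(i)) stop("empty current trace")
    if (mode == "peak") i[which.max(abs(i))]
    else mean(tail(i, max(1L, round(end_fraction * length(i)))))
  }, numeric(1))
  out <- data.frame(test_potential = v, current_density = val / capacitance)
  out <- out[order(out$test_potential), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, capacitance = capacitance, mode = mode,
            class = c("iv_curve", "data.frame"))
}

#' Subtract linear leak from an IV curve
#'
#' Fits current density against potential over a sub-threshold fitting
#' range (where only ohmic leak flows) and subtracts the fitted line from
#' the whole curve; a purely ohmic curve maps to zero at all potentials.
#' The fitting range is a logged analysis parameter.
#'
#' @param curve an `iv_curve`
#' @param fit_range numeric length-2, potential range (mV) of the leak fit
#' @return leak-subtracted `iv_curve`
#' @export
leak_subtract <- function(curve, fit_range) {
  stopifnot(inherits(curve, "iv_curve"), length(fit_range) == 2L)
  sel <- curve$test_potential >= min(fit_range) &
         curve$test_potential <= max(fit_range)
  if (sum(sel) < 2L) stop("need >= 2 points inside the leak fitting range")
  message(sprintf("leak fit over [%g, %g] mV (%d points)",
                  min(fit_range), max(fit_range), sum(sel)))
  fit <- lm(current_density ~ test_potential, data = curve[sel, , drop = FALSE])
  curve$current_density <- curve$current_density -
    predict(fit, newdata = curve["test_potential"])
  curve
}

#' Drug-sensitive current by IV subtraction
#'
#' Pointwise control minus drug current density on an identical
#' test-potential grid; isolates the drug-sensitive component (e.g. the
#' chromanol-sensitive slow delayed-rectifier current).
#'
#' @param control,drug `iv_curve` objects on the same potential grid
#' @return `iv_curve` of the difference
#' @export
drug_subtract <- function(control, drug) {
  stopifnot(inherits(control, "iv_curve"), inherits(drug, "iv_curve"))
  if (!isTRUE(all.equal(control$test_potential, drug$test_potential)))
    stop("control and drug curves must share the same test-potential grid")
  control$current_density <- control$current_density - drug$current_density
  control
}
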