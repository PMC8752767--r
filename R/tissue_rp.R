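# Effective refractory period (RP) of paced myocardial tissue from
# twitch-force recordings: the programmed S1-S2 stimulation schedule, twitch
# detection, per-pair and per-block classification, and the RP decision rule
# (longest interstimulus interval that fails to evoke two distinct
# contractions).

#' Programmed S1-S2 stimulation schedule
#'
#' Blocks of constant interstimulus interval, decreasing from `start_ms`
#' towards `stop_ms` in steps of `step_ms`; each block lasts
#' `block_duration_s` seconds at the S1 pacing rate, so a block holds
#' `block_duration_s * s1_rate_hz` S1-S2 pairs.
#'
#' @param start_ms longest tested interval
#' @param stop_ms shortest tested interval (inclusive when on the step grid)
#' @param step_ms decrement between blocks (no default: protocol parameter)
#' @param block_duration_s duration of each block
#' @param s1_rate_hz basic pacing rate
#' @return object of class `stimulation_schedule`: data.frame(interval,
#'   block_duration_s, n_pairs) plus `s1_rate_hz` attribute
#' @examples
#' build_schedule(step_ms = 50)  # 16 blocks: 1000, 950, ..., 250 ms
#' @export
build_schedule <- function(start_ms = 1000, stop_ms = 250, step_ms,
                           block_duration_s = 20, s1_rate_hz = 0.5) {
  stopifnot_scalar_num(step_ms, "step_ms", positive = TRUE)
  if (start_ms <= stop_ms) stop("start_ms must exceed stop_ms")
  intervals <- seq(start_ms, stop_ms, by = -step_ms)
  n_pairs <- round(block_duration_s * s1_rate_hz)
  if (n_pairs < 1L) stop("block too short for one S1-S2 pair")
  structure(data.frame(interval = intervals,
                       block_duration_s = block_duration_s,
                       n_pairs = n_pairs),
            s1_rate_hz = s1_rate_hz,
            class = c("stimulation_schedule", "data.frame"))
}

#' Twitch-analysis configuration
#'
#' The reading criteria are logged analysis parameters: a peak counts as a
#' twitch when its prominence reaches `min_prominence_fraction` of the
#' reference twitch amplitude (median S1-only twitch of the pre-protocol
#' baseline); a response is attributed to a stimulus when its peak falls
#' within `response_latency_ms`; two peaks are "distinct contractions" when
#' the valley between them drops below `valley_fraction` of the smaller
#' peak (above local pre-stimulus baseline).
#'
#' @param min_prominence_fraction minimum peak prominence, as a fraction of
#'   the reference twitch amplitude
#' @param min_peak_separation_ms minimum separation between reported peaks
#' @param response_latency_ms stimulus-to-peak attribution window
#' @param valley_fraction relative valley depth required between twin peaks
#' @param smooth_ms moving-average width applied before peak picking
#' @return list of class `rp_config`
#' @export
rp_config <- function(min_prominence_fraction = 0.2,
                      min_peak_separation_ms = 100,
                      response_latency_ms = 300,
                      valley_fraction = 0.5,
                      smooth_ms = 40) {
  structure(list(min_prominence_fraction = min_prominence_fraction,
                 min_peak_separation_ms = min_peak_separation_ms,
                 response_latency_ms = response_latency_ms,
                 valley_fraction = valley_fraction,
                 smooth_ms = smooth_ms), class = "rp_config")
}

#' Force-trace container
#'
#' @param time time stamps (ms), uniformly sampled
#' @param force contraction force (mN)
#' @param stimuli data.frame(time_ms, type, block): type "S1"/"S2";
#'   block 0 denotes the pre-protocol S1-only baseline
#' @return object of class `force_trace`
#' @export
force_trace <- function(time, force, stimuli) {
  stopifnot(length(time) == length(force),
            is.data.frame(stimuli),
            all(c("time_ms", "type", "block") %in% names(stimuli)))
  if (nrow(stimuli) &&
      (min(stimuli$time_ms) < min(time) || max(stimuli$time_ms) > max(time)))
    stop("stimulus times must lie within the trace span")
  structure(list(time = time, force = force,
                 sampling_interval = median(diff(time)),
                 stimuli = stimuli), class = "force_trace")
}

# Local maxima with prominences on a plain numeric vector.
# Prominence of a peak: height above the higher of the two minima separating
# it from the nearest higher point (or the window edge).
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  up <- diff(y) > 0
  cand <- which(c(FALSE, up) & c(!up, FALSE))  # strict local maxima
  if (!length(cand)) return(data.frame(index = integer(0), height = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    hi_l <- which(left > h)
    lo <- if (length(hi_l)) min(left[(max(hi_l) + 1L):(p - 1L)]) else min(left)
    right <- y[(p + 1L):n]
    hi_r <- which(right > h)
    hi_val <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1L)]) else min(right)
    h - max(lo, hi_val)
  }, numeric(1))
  data.frame(index = cand, height = y[cand], prominence = prom)
}

#' Detect twitches in a force-trace window
#'
#' Smooths the force signal and reports peaks whose prominence reaches the
#' configured fraction of the reference twitch amplitude, thinning peaks
#' closer than the minimum separation (the more prominent one wins).
#'
#' @param trace a `force_trace`
#' @param window numeric length-2, time window (ms)
#' @param reference_amplitude reference twitch amplitude (mN); see
#'   [refractory_period()] for how it is estimated from the baseline period
#' @param config an `rp_config`
#' @return data.frame(peak_time, peak_force, prominence)
#' @export
detect_twitches <- function(trace, window, reference_amplitude,
                            config = rp_config()) {
  stopifnot(inherits(trace, "force_trace"), length(window) == 2L)
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(sel) < 3L)
    return(data.frame(peak_time = numeric(0), peak_force = numeric(0),
                      prominence = numeric(0)))
  t <- trace$time[sel]
  y <- moving_avg(trace$force[sel], round(config$smooth_ms / trace$sampling_interval))
  pk <- find_peaks(y)
  pk <- pk[pk$prominence >= config$min_prominence_fraction * reference_amplitude, ,
           drop = FALSE]
  if (nrow(pk) > 1L) {
    pk <- pk[order(-pk$prominence), , drop = FALSE]
    keep <- logical(nrow(pk))
    taken <- numeric(0)
    for (i in seq_len(nrow(pk))) {
      tt <- t[pk$index[i]]
      if (!length(taken) || all(abs(taken - tt) >= config$min_peak_separation_ms)) {
        keep[i] <- TRUE; taken <- c(taken, tt)
      }
    }
    pk <- pk[keep, , drop = FALSE]
    pk <- pk[order(pk$index), , drop = FALSE]
  }
  data.frame(peak_time = t[pk$index], peak_force = y[pk$index],
             prominence = pk$prominence, row.names = NULL)
}

#' Did an S1-S2 pair evoke two distinct contractions?
#'
#' TRUE iff twitch detection over the pair window finds at least two peaks,
#' with one attributable to each stimulus (peak within the configured
#' response latency after its stimulus) and the inter-peak valley dropping
#' below `valley_fraction` of the smaller peak height above the local
#' pre-stimulus baseline (a fused broad twitch fails this).
#'
#' @param trace a `force_trace`
#' @param s1_time,s2_time stimulus times (ms)
#' @param reference_amplitude reference twitch amplitude (mN)
#' @param config an `rp_config`
#' @return logical
#' @export
classify_pair <- function(trace, s1_time, s2_time, reference_amplitude,
                          config = rp_config()) {
  stopifnot(s2_time > s1_time)
  win <- c(s1_time - 50, s2_time + config$response_latency_ms + 200)
  tw <- detect_twitches(trace, win, reference_amplitude, config)
  if (nrow(tw) < 2L) return(FALSE)
  p1 <- tw[tw$peak_time > s1_time &
             tw$peak_time <= s1_time + config$response_latency_ms, , drop = FALSE]
  p2 <- tw[tw$peak_time > s2_time &
             tw$peak_time <= s2_time + config$response_latency_ms, , drop = FALSE]
  # S1 and S2 windows may overlap at short intervals: require two different peaks
  if (!nrow(p1) || !nrow(p2)) return(FALSE)
  t1 <- p1$peak_time[which.max(p1$prominence)]
  p2 <- p2[p2$peak_time > t1, , drop = FALSE]
  if (!nrow(p2)) return(FALSE)
  t2 <- p2$peak_time[which.max(p2$prominence)]
  # valley test on the smoothed signal between the two peaks
  sel <- trace$time >= win[1] & trace$time <= win[2]
  tt <- trace$time[sel]
  y <- moving_avg(trace$force[sel], round(config$smooth_ms / trace$sampling_interval))
  base_sel <- tt >= s1_time - 50 & tt <= s1_time
  base <- if (any(base_sel)) min(y[base_sel]) else min(y)
  h1 <- y[which.min(abs(tt - t1))] - base
  h2 <- y[which.min(abs(tt - t2))] - base
  valley <- min(y[tt > t1 & tt < t2]) - base
  valley < config$valley_fraction * min(h1, h2)
}

#' Effective refractory period from a programmed-stimulation recording
#'
#' Classifies every S1-S2 pair of every schedule block, calls a block
#' "two distinct contractions" by strict majority over its pairs, and
#' reports the RP as the longest interval whose block failed. When no block
#' fails the RP lies below the shortest tested interval (censored
#' `"below_min"`); when all blocks fail it lies above the longest
#' (censored `"above_max"`). Blocks without detectable S1 twitches are
#' excluded with a warning. The reference twitch amplitude is the median
#' prominence of S1-evoked twitches in the pre-protocol baseline period
#' (block 0), falling back to the first block's S1 twitches if no baseline
#' was recorded.
#'
#' @param trace a `force_trace` with stimulus annotations
#' @param schedule the `stimulation_schedule` used
#' @param config an `rp_config`
#' @return object of class `rp_result`: list(rp, censored, per_block,
#'   reference_amplitude); `rp` is NA when censored
#' @export
refractory_period <- function(trace, schedule, config = rp_config()) {
  stopifnot(inherits(trace, "force_trace"),
            inherits(schedule, "stimulation_schedule"))
  stim <- trace$stimuli
  ref <- .reference_amplitude(trace, config)
  per_block <- lapply(seq_len(nrow(schedule)), function(b) {
    s1 <- stim$time_ms[stim$block == b & stim$type == "S1"]
    s2 <- stim$time_ms[stim$block == b & stim$type == "S2"]
    if (!length(s1) || length(s1) != length(s2))
      stop("block ", b, ": malformed stimulus annotation")
    two <- mapply(function(a, z) classify_pair(trace, a, z, ref, config), s1, s2)
    n_s1_detected <- sum(vapply(s1, function(a) {
      nrow(detect_twitches(trace, c(a, a + config$response_latency_ms),
                           ref, config)) > 0L
    }, logical(1)))
    data.frame(interval = schedule$interval[b], n_pairs = length(s1),
               n_pairs_with_two = sum(two),
               evoked_two_contractions = sum(two) > length(s1) / 2,
               n_s1_detected = n_s1_detected)
  })
  per_block <- do.call(rbind, per_block)
  usable <- per_block$n_s1_detected > 0L
  if (any(!usable))
    warning(sum(!usable), " block(s) without detectable S1 twitches excluded")
  pb <- per_block[usable, , drop = FALSE]
  failed <- pb$interval[!pb$evoked_two_contractions]
  if (!length(failed)) {
    rp <- NA_real_; censored <- "below_min"
  } else if (all(!pb$evoked_two_contractions)) {
    rp <- NA_real_; censored <- "above_max"
  } else {
    rp <- max(failed); censored <- NA_character_
  }
  structure(list(rp = rp, censored = censored, per_block = per_block,
                 reference_amplitude = ref), class = "rp_result")
}

.reference_amplitude <- function(trace, config) {
  stim <- trace$stimuli
  s1_base <- stim$time_ms[stim$block == 0 & stim$type == "S1"]
  if (!length(s1_base)) {
    b1 <- min(stim$block[stim$block > 0])
    s1_base <- stim$time_ms[stim$block == b1 & stim$type == "S1"]
  }
  if (!length(s1_base)) stop("no S1 stimuli to estimate the reference twitch")
  proms <- unlist(lapply(s1_base, function(a) {
    sel <- trace$time >= a & trace$time <= a + config$response_latency_ms + 200
    if (sum(sel) < 3L) return(numeric(0))
    y <- moving_avg(trace$force[sel],
                    round(config$smooth_ms / trace$sampling_interval))
    pk <- find_peaks(y)
    if (nrow(pk)) max(pk$prominence) else numeric(0)
  }))
  if (!length(proms)) stop("no detectable reference twitches")
  median(proms)
}

#' @export
print.rp_result <- function(x, ...) {
  if (is.na(x$rp))
    cat("Refractory period: censored (", x$censored, ")\n", sep = "")
  else
    cat("Refractory period:", x$rp, "ms\n")
  cat("  blocks:", nrow(x$per_block), " failing:",
      sum(!x$per_block$evoked_two_contractions), "\n")
  invisible(x)
}

#' Paired refractory-period change
#'
#' Difference of two RP estimates (post - pre), e.g. around a miRNA mimic
#' or antimiR transfection. NA when either measurement is censored.
#'
#' @param post,pre `rp_result` objects
#' @return difference in ms
#' @export
rp_delta <- function(post, pre) {
  stopifnot(inherits(post, "rp_result"), inherits(pre, "rp_result"))
  post$rp - pre$rp
}
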