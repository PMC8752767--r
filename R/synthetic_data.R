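# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth recorded BEFORE noise injection, so
# downstream recovery is testable exactly (noiseless) or to stated bounds
# (noisy). All generators are deterministic under `rng_seed` and leave the
# caller's RNG stream untouched.

#' Random, mutually compatible seed families
#'
#' Draws distinct random 7-nt seeds and rejects pools in which any
#' canonical site string of one family occurs inside another family's site
#' strings (which would make exact planted-site bookkeeping impossible).
#'
#' @param n number of families
#' @param rng_seed RNG seed
#' @return data.frame(family_id, seed)
#' @export
random_seed_families <- function(n, rng_seed = NULL) {
  with_seed(rng_seed, {
    repeat {
      seeds <- unique(vapply(seq_len(2L * n + 4L), function(i)
        paste(sample(c("A", "C", "G", "U"), 7L, replace = TRUE), collapse = ""),
        character(1)))
      if (length(seeds) < n) next
      seeds <- seeds[seq_len(n)]
      strs <- lapply(seeds, function(s) unname(site_sequences(s, "DNA")))
      ok <- TRUE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        for (a in strs[[i]]) for (b in strs[[j]])
          if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)) ok <- FALSE
      }
      if (ok) break
    }
    data.frame(family_id = sprintf("F%02d", seq_len(n)), seed = seeds,
               stringsAsFactors = FALSE)
  })
}

#' Simulate 3' UTR sequences with planted canonical sites
#'
#' Generates one random UTR per gene at the requested GC content and plants
#' the requested canonical sites at random non-overlapping positions
#' (recorded in the returned ground-truth table). Background sequence is
#' then rejection-sampled against the whole family pool: any window that
#' the canonical-site scanner would report beyond the planted ones is
#' redrawn, so ground-truth counts are exact by construction, not
#' statistically.
#'
#' @param n_genes number of genes
#' @param utr_length UTR length in nt
#' @param family_pool data.frame(family_id, seed); every planted family
#'   must appear here
#' @param planted_sites data.frame(gene_id, family_id, site_type) with
#'   site_type in 8mer/7mer-m8/7mer-A1; may be empty
#' @param gc_content background GC fraction
#' @param rng_seed RNG seed
#' @param max_iter rejection-sampling iteration cap per gene
#' @return list(utrs = named character vector of DNA sequences,
#'   sites = ground-truth data.frame(gene_id, family_id, site_type, start,
#'   end), families = family_pool)
#' @export
simulate_utrs <- function(n_genes, utr_length, family_pool,
                          planted_sites = NULL, gc_content = 0.5,
                          rng_seed = NULL, max_iter = 200L) {
  stopifnot(n_genes >= 1L, utr_length >= 8L,
            gc_content >= 0, gc_content <= 1,
            is.data.frame(family_pool),
            all(c("family_id", "seed") %in% names(family_pool)))
  genes <- sprintf("g%03d", seq_len(n_genes))
  if (is.null(planted_sites))
    planted_sites <- data.frame(gene_id = character(0),
                                family_id = character(0),
                                site_type = character(0))
  stopifnot(all(c("gene_id", "family_id", "site_type") %in% names(planted_sites)))
  if (!all(planted_sites$family_id %in% family_pool$family_id))
    stop("planted site references a family absent from the pool")
  if (!all(planted_sites$site_type %in% c("8mer", "7mer-m8", "7mer-A1")))
    stop("unknown site_type in planted_sites")
  if (!all(planted_sites$gene_id %in% genes))
    stop("planted site references a gene beyond n_genes (ids are g001..)")
  site_str <- lapply(stats::setNames(family_pool$seed, family_pool$family_id),
                     site_sequences, alphabet = "DNA")
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)

  with_seed(rng_seed, {
    truth <- vector("list", n_genes)
    utrs <- character(n_genes)
    for (gi in seq_len(n_genes)) {
      g <- genes[gi]
      plant <- planted_sites[planted_sites$gene_id == g, , drop = FALSE]
      k <- nrow(plant)
      lens <- if (k) ifelse(plant$site_type == "8mer", 8L, 7L) else integer(0)
      if (sum(lens) + max(k - 1L, 0L) > utr_length)
        stop("infeasible planting for gene ", g, ": ", k,
             " site(s) need more than ", utr_length, " nt")
      ok <- FALSE
      for (iter in seq_len(max_iter)) {
        # random non-overlapping placement with >= 1 nt separation
        if (k) {
          ord <- sample.int(k)
          free <- utr_length - sum(lens) - (k - 1L)
          gaps <- as.integer(stats::rmultinom(1L, free, rep(1, k + 1L)))
          starts0 <- cumsum(c(gaps[1L],
                              utils::head(lens[ord], -1L) + 1L +
                                gaps[2:k][seq_len(max(k - 1L, 0L))]))
          if (k == 1L) starts0 <- gaps[1L]
          starts <- integer(k); starts[ord] <- starts0
        } else starts <- integer(0)
        bg <- sample(names(probs), utr_length, replace = TRUE, prob = probs)
        seq_chars <- bg
        planted_pos <- logical(utr_length)
        for (s in seq_len(k)) {
          str <- site_str[[plant$family_id[s]]][[plant$site_type[s]]]
          idx <- (starts[s] + 1L):(starts[s] + nchar(str))
          seq_chars[idx] <- strsplit(str, "")[[1L]]
          planted_pos[idx] <- TRUE
        }
        want <- if (k) data.frame(family_id = plant$family_id,
                                  site_type = plant$site_type,
                                  start = starts,
                                  end = starts + lens,
                                  stringsAsFactors = FALSE)
                else data.frame(family_id = character(0),
                                site_type = character(0),
                                start = integer(0), end = integer(0))
        # redraw offending background bases until the scan is exactly
        # the planted set
        clean <- FALSE
        for (sub in seq_len(50L)) {
          utr <- paste(seq_chars, collapse = "")
          got <- do.call(rbind, lapply(family_pool$family_id, function(f) {
            h <- .scan_core(utr, family_pool$seed[family_pool$family_id == f])
            if (nrow(h)) cbind(family_id = f, h) else NULL
          }))
          if (is.null(got))
            got <- data.frame(family_id = character(0),
                              site_type = character(0),
                              start = integer(0), end = integer(0))
          key <- function(d) paste(d$family_id, d$site_type, d$start)
          extra <- got[!(key(got) %in% key(want)), , drop = FALSE]
          missing <- want[!(key(want) %in% key(got)), , drop = FALSE]
          if (!nrow(extra) && !nrow(missing)) { clean <- TRUE; break }
          touch <- unique(unlist(mapply(seq, extra$start + 1L, extra$end,
                                        SIMPLIFY = FALSE)))
          touch <- union(touch,
                         unique(unlist(mapply(seq, missing$start + 1L,
                                              missing$end, SIMPLIFY = FALSE))))
          touch <- touch[!planted_pos[touch]]
          if (!length(touch)) break  # conflict inside planted bases: re-place
          seq_chars[touch] <- sample(names(probs), length(touch),
                                     replace = TRUE, prob = probs)
          # restore planted windows (a missing site means background around
          # it changed its call; planted bases themselves are untouched)
        }
        if (clean) { ok <- TRUE; break }
      }
      if (!ok) stop("could not realize planted sites for gene ", g,
                    " without spurious matches; check family pool for ",
                    "conflicting seeds")
      utrs[gi] <- paste(seq_chars, collapse = "")
      if (k) truth[[gi]] <- cbind(gene_id = g, want)
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth))
      truth <- data.frame(gene_id = character(0), family_id = character(0),
                          site_type = character(0), start = integer(0),
                          end = integer(0))
    truth <- truth[order(truth$gene_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(utrs = stats::setNames(utrs, genes), sites = truth,
         families = family_pool)
  })
}

#' Simulate paired abundance tables with a planted top-N intersection
#'
#' Emulates dual expression profiles (e.g. cultured myocytes and adult
#' myocardium): exactly `n_expressed_in_both` entities rank in the top-`n_top`
#' of both tables. Requires `n_entities >= 2 * n_top - n_expressed_in_both`
#' so the non-shared top slots can be filled disjointly.
#'
#' @param n_entities total number of entities
#' @param n_top size of each top list
#' @param n_expressed_in_both planted intersection size
#' @param rng_seed RNG seed
#' @param prefix id prefix
#' @return list(table_a, table_b, shared): tables are
#'   data.frame(id, abundance) in random row order
#' @export
simulate_expression <- function(n_entities, n_top = 100L, n_expressed_in_both,
                                rng_seed = NULL, prefix = "mir") {
  stopifnot(n_expressed_in_both <= n_top, n_top <= n_entities)
  if (n_entities < 2L * n_top - n_expressed_in_both)
    stop("need n_entities >= 2 * n_top - n_expressed_in_both to keep the ",
         "planted intersection exact")
  with_seed(rng_seed, {
    ids <- sprintf("%s%04d", prefix, seq_len(n_entities))
    shared <- sample(ids, n_expressed_in_both)
    rest <- setdiff(ids, shared)
    fill_a <- if (n_top > n_expressed_in_both)
      sample(rest, n_top - n_expressed_in_both) else character(0)
    fill_b <- if (n_top > n_expressed_in_both)
      sample(setdiff(rest, fill_a), n_top - n_expressed_in_both) else character(0)
    mk <- function(top_ids) {
      low_ids <- setdiff(ids, top_ids)
      ranked <- c(sample(top_ids), sample(low_ids))
      ab <- 1e4 * exp(-0.05 * (seq_along(ranked) - 1L))
      tb <- data.frame(id = ranked, abundance = ab, stringsAsFactors = FALSE)
      tb[sample.int(nrow(tb)), , drop = FALSE]
    }
    list(table_a = mk(c(shared, fill_a)), table_b = mk(c(shared, fill_b)),
         shared = sort(shared))
  })
}

#' Simulate an optical action-potential trace with analytic ground truth
#'
#' Piecewise-linear AP shape per beat: baseline -> linear upstroke ->
#' plateau at baseline + amplitude -> linear repolarization -> baseline.
#' The analytic APD at level l (time from upstroke onset to the crossing of
#' baseline + (1-l) x amplitude on the falling limb) is
#' upstroke + plateau + l x repolarization; it is recorded per beat before
#' additive white noise and linear drift (photobleaching) are applied.
#' `upstroke_duration = 0` gives an instant rise.
#'
#' @param n_beats number of beats (0 gives a flat baseline trace)
#' @param baseline,amplitude signal units; amplitude > 0
#' @param upstroke_duration,plateau_duration,repolarization_duration ms
#' @param beat_interval inter-beat interval (ms); must exceed the waveform
#'   duration
#' @param sampling_interval ms; must resolve a non-instant upstroke
#' @param noise_sd additive white-noise SD (signal units)
#' @param drift_per_s linear drift slope (signal units per second)
#' @param lead_in_ms,tail_ms flat padding before the first / after the last
#'   beat
#' @param two_channel also return raw fluorescence channels whose ratio
#'   reproduces the signal
#' @param rng_seed RNG seed
#' @return list(trace = `ratio_trace`, truth = data.frame(beat, onset_ms,
#'   apd90_ms, rr_ms), channels (optional), params)
#' @export
simulate_ap_trace <- function(n_beats = 10L, baseline = 1, amplitude = 1,
                              upstroke_duration = 10, plateau_duration = 150,
                              repolarization_duration = 250,
                              beat_interval = 1000, sampling_interval = 2,
                              noise_sd = 0, drift_per_s = 0,
                              lead_in_ms = 500, tail_ms = 500,
                              two_channel = FALSE, rng_seed = NULL) {
  stopifnot_scalar_num(amplitude, "amplitude", positive = TRUE)
  stopifnot_scalar_num(sampling_interval, "sampling_interval", positive = TRUE)
  stopifnot_scalar_num(repolarization_duration, "repolarization_duration",
                       positive = TRUE)
  wav <- upstroke_duration + plateau_duration + repolarization_duration
  if (n_beats > 0L && beat_interval <= wav)
    stop("beat_interval must exceed the waveform duration (",
         wav, " ms)")
  if (upstroke_duration > 0 && sampling_interval > upstroke_duration)
    stop("sampling_interval too coarse to represent the upstroke")
  total <- lead_in_ms + max(n_beats, 0L) * beat_interval + tail_ms
  time <- seq(0, total, by = sampling_interval)
  signal <- rep(baseline, length(time))
  truth <- NULL
  if (n_beats > 0L) {
    onsets <- lead_in_ms + (seq_len(n_beats) - 1L) * beat_interval
    for (on in onsets) {
      ph <- time - on
      in_up <- upstroke_duration > 0 & ph >= 0 & ph < upstroke_duration
      in_pl <- ph >= upstroke_duration & ph < upstroke_duration + plateau_duration
      in_rp <- ph >= upstroke_duration + plateau_duration & ph < wav
      signal[in_up] <- baseline + amplitude * ph[in_up] / upstroke_duration
      signal[in_pl] <- baseline + amplitude
      signal[in_rp] <- baseline + amplitude *
        (1 - (ph[in_rp] - upstroke_duration - plateau_duration) /
           repolarization_duration)
    }
    truth <- data.frame(
      beat = seq_len(n_beats),
      onset_ms = onsets,
      apd90_ms = upstroke_duration + plateau_duration +
        0.9 * repolarization_duration,
      rr_ms = c(NA_real_, rep(beat_interval, n_beats - 1L)))
  } else {
    truth <- data.frame(beat = integer(0), onset_ms = numeric(0),
                        apd90_ms = numeric(0), rr_ms = numeric(0))
  }
  signal <- with_seed(rng_seed,
    signal + drift_per_s * time / 1000 +
      if (noise_sd > 0) rnorm(length(time), 0, noise_sd) else 0)
  trace <- as_trace(time, signal)
  channels <- NULL
  if (two_channel) {
    den <- rep(2, length(time))
    channels <- list(numerator = signal * den, denominator = den)
  }
  list(trace = trace, truth = truth, channels = channels,
       params = list(baseline = baseline, amplitude = amplitude,
                     upstroke_duration = upstroke_duration,
                     plateau_duration = plateau_duration,
                     repolarization_duration = repolarization_duration,
                     beat_interval = beat_interval,
                     sampling_interval = sampling_interval,
                     noise_sd = noise_sd, drift_per_s = drift_per_s))
}

#' Simulate a twitch-force recording under a programmed S1-S2 protocol
#'
#' Every S1 evokes a full twitch (a normalized double-exponential kernel);
#' an S2 evokes a full twitch iff its interstimulus interval exceeds
#' `true_rp`, otherwise a twitch scaled by `refractory_response_fraction`
#' (0 by default: the hard binary rule). A pre-protocol S1-only baseline
#' period provides the reference twitch. Stimulus timestamps are returned
#' with the trace; `true_rp` is the recorded ground truth.
#'
#' @param true_rp ground-truth refractory period (ms)
#' @param schedule a `stimulation_schedule`
#' @param twitch_peak peak twitch force (mN)
#' @param twitch_rise_ms,twitch_decay_ms kernel time constants
#' @param refractory_response_fraction fraction of a full twitch evoked by
#'   a refractory S2
#' @param noise_sd additive force noise SD (mN)
#' @param sampling_interval ms
#' @param baseline_s duration of the pre-protocol S1-only period
#' @param rng_seed RNG seed
#' @return list(trace = `force_trace`, true_rp)
#' @export
simulate_force_trace <- function(true_rp, schedule, twitch_peak = 1,
                                 twitch_rise_ms = 40, twitch_decay_ms = 120,
                                 refractory_response_fraction = 0,
                                 noise_sd = 0, sampling_interval = 5,
                                 baseline_s = 10, rng_seed = NULL) {
  stopifnot(inherits(schedule, "stimulation_schedule"))
  stopifnot_scalar_num(true_rp, "true_rp", positive = TRUE)
  stopifnot(refractory_response_fraction >= 0,
            refractory_response_fraction <= 1,
            twitch_decay_ms > twitch_rise_ms)
  rate <- attr(schedule, "s1_rate_hz")
  period <- 1000 / rate
  t0 <- 500
  stim <- list()
  amp <- numeric(0)
  n_base <- round(baseline_s * rate)
  if (n_base > 0L) {
    s1 <- t0 + (seq_len(n_base) - 1L) * period
    stim[[1L]] <- data.frame(time_ms = s1, type = "S1", block = 0L)
    amp <- c(amp, rep(1, n_base))
  }
  cur <- t0 + n_base * period
  for (b in seq_len(nrow(schedule))) {
    iv <- schedule$interval[b]
    np <- schedule$n_pairs[b]
    s1 <- cur + (seq_len(np) - 1L) * period
    s2 <- s1 + iv
    resp <- if (iv > true_rp) 1 else refractory_response_fraction
    stim[[length(stim) + 1L]] <-
      data.frame(time_ms = c(rbind(s1, s2)),
                 type = rep(c("S1", "S2"), np),
                 block = b)
    amp <- c(amp, rep(c(1, resp), np))
    cur <- cur + np * period
  }
  stim <- do.call(rbind, stim)
  total <- cur + 1000
  time <- seq(0, total, by = sampling_interval)
  force <- numeric(length(time))
  # normalized double-exponential twitch kernel
  tp <- log(twitch_decay_ms / twitch_rise_ms) * twitch_rise_ms *
    twitch_decay_ms / (twitch_decay_ms - twitch_rise_ms)
  gmax <- exp(-tp / twitch_decay_ms) - exp(-tp / twitch_rise_ms)
  klen <- ceiling(6 * twitch_decay_ms / sampling_interval)
  for (s in seq_len(nrow(stim))) {
    if (amp[s] <= 0) next
    i0 <- floor(stim$time_ms[s] / sampling_interval) + 1L
    idx <- i0:min(i0 + klen, length(time))
    dt_s <- time[idx] - stim$time_ms[s]
    dt_s[dt_s < 0] <- 0
    force[idx] <- force[idx] + amp[s] * twitch_peak *
      (exp(-dt_s / twitch_decay_ms) - exp(-dt_s / twitch_rise_ms)) / gmax
  }
  force <- with_seed(rng_seed,
    force + if (noise_sd > 0) rnorm(length(time), 0, noise_sd) else 0)
  list(trace = force_trace(time, force, stim), true_rp = true_rp)
}

#' Simulate a differential-expression table with planted target shift
#'
#' Non-target genes draw log2 fold changes from Normal(0, sd); target genes
#' from Normal(target_shift, sd). FDR values are generated consistently
#' with the fold changes (Wald-style p from |log2FC| / sd, BH-adjusted), so
#' genes with larger shifts get smaller FDR on average. With
#' `target_shift = 0` and `frac_null_de = 0`, targets and non-targets are
#' exchangeable.
#'
#' @param n_genes total genes
#' @param n_targets number of planted targets (<= n_genes)
#' @param target_shift mean target log2FC (negative = repression)
#' @param sd_log2fc log2FC standard deviation (> 0)
#' @param frac_null_de fraction of non-targets that are truly DE, given an
#'   extra shift of +/- `null_de_shift`
#' @param null_de_shift magnitude of the non-target DE shift
#' @param rng_seed RNG seed
#' @return list(table = data.frame(gene_id, log2fc, fdr), target_ids,
#'   is_target)
#' @export
simulate_de_table <- function(n_genes, n_targets, target_shift = 0,
                              sd_log2fc = 0.3, frac_null_de = 0,
                              null_de_shift = 1, rng_seed = NULL) {
  stopifnot(n_targets <= n_genes, sd_log2fc > 0,
            frac_null_de >= 0, frac_null_de <= 1)
  with_seed(rng_seed, {
    ids <- sprintf("g%05d", seq_len(n_genes))
    is_target <- rep(FALSE, n_genes)
    if (n_targets > 0L) is_target[sample.int(n_genes, n_targets)] <- TRUE
    lfc <- rnorm(n_genes, 0, sd_log2fc)
    lfc[is_target] <- lfc[is_target] + target_shift
    nt <- which(!is_target)
    n_de <- round(frac_null_de * length(nt))
    if (n_de > 0L) {
      de <- sample(nt, n_de)
      lfc[de] <- lfc[de] + sample(c(-1, 1), n_de, replace = TRUE) * null_de_shift
    }
    p <- 2 * pnorm(-abs(lfc) / sd_log2fc)
    list(table = data.frame(gene_id = ids, log2fc = lfc,
                            fdr = p.adjust(p, method = "BH"),
                            stringsAsFactors = FALSE),
         target_ids = ids[is_target], is_target = is_target)
  })
}

#' Simulate per-cell reporter intensities for two arms
#'
#' Control-arm GFP/RFP ratios center at `control_mean_ratio`; treated-arm
#' ratios at `control_mean_ratio * repression_factor`. Multiplicative
#' lognormal cell-to-cell noise of coefficient of variation `cv` applies
#' to both channels (it cancels between arms in the normalized ratio);
#' `cv = 0` is exact. A mutated-UTR specificity arm is the same generator
#' with `repression_factor = 1`.
#'
#' @param n_cells cells per arm
#' @param repression_factor in (0, 1]
#' @param control_mean_ratio mean control GFP/RFP ratio
#' @param cv coefficient of variation of the per-cell ratio
#' @param rfp_mean mean RFP intensity (arbitrary units)
#' @param rng_seed RNG seed
#' @return list(treated, control): data.frames(cell_id, gfp, rfp, condition)
#' @export
simulate_reporter_cells <- function(n_cells, repression_factor,
                                    control_mean_ratio = 1, cv = 0.1,
                                    rfp_mean = 1000, rng_seed = NULL) {
  stopifnot(repression_factor > 0, repression_factor <= 1, cv >= 0,
            n_cells >= 1L)
  with_seed(rng_seed, {
    arm <- function(factor, label) {
      rfp <- rfp_mean * exp(if (cv > 0) rnorm(n_cells, 0, cv) else 0)
      ratio <- control_mean_ratio * factor *
        exp(if (cv > 0) rnorm(n_cells, 0, cv) else 0)
      data.frame(cell_id = sprintf("%s_%04d", label, seq_len(n_cells)),
                 gfp = rfp * ratio, rfp = rfp, condition = label,
                 stringsAsFactors = FALSE)
    }
    list(treated = arm(repression_factor, "treated"),
         control = arm(1, "control"))
  })
}
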