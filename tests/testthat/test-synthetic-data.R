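test_that("generators are reproducible under a fixed seed", {
  f1 <- random_seed_families(3, rng_seed = 9)
  f2 <- random_seed_families(3, rng_seed = 9)
  expect_identical(f1, f2)
  plant <- data.frame(gene_id = "g001", family_id = "F01", site_type = "8mer")
  expect_identical(simulate_utrs(2, 100, f1, plant, rng_seed = 4),
                   simulate_utrs(2, 100, f1, plant, rng_seed = 4))
  expect_identical(simulate_ap_trace(n_beats = 3, noise_sd = 0.05,
                                     rng_seed = 5),
                   simulate_ap_trace(n_beats = 3, noise_sd = 0.05,
                                     rng_seed = 5))
  expect_identical(simulate_de_table(50, 5, rng_seed = 6),
                   simulate_de_table(50, 5, rng_seed = 6))
})

test_that("UTR generator records exactly the planted sites", {
  fams <- random_seed_families(3, rng_seed = 21)
  # empty plant
  s0 <- simulate_utrs(3, 80, fams, rng_seed = 22)
  expect_equal(nrow(s0$sites), 0L)
  # single 8mer
  plant <- data.frame(gene_id = "g002", family_id = "F02", site_type = "8mer")
  s1 <- simulate_utrs(3, 80, fams, plant, rng_seed = 23)
  expect_equal(s1$sites[, c("gene_id", "family_id", "site_type")],
               plant, ignore_attr = TRUE)
  # the planted window holds the literal site string
  str <- site_sequences(fams$seed[2], "DNA")[["8mer"]]
  expect_equal(substr(s1$utrs[["g002"]], s1$sites$start + 1, s1$sites$end), str)
  # infeasible planting is reported
  many <- data.frame(gene_id = "g001", family_id = "F01",
                     site_type = rep("8mer", 5))
  expect_error(simulate_utrs(1, 20, fams, many), "infeasible")
})

test_that("scanner recovers generator ground truth gene by gene", {
  fams <- random_seed_families(5, rng_seed = 61)
  set.seed(62)
  plant <- do.call(rbind, lapply(1:20, function(g) {
    k <- sample(2:3, 1)
    data.frame(gene_id = sprintf("g%03d", g),
               family_id = sample(fams$family_id, k, replace = TRUE),
               site_type = sample(c("8mer", "7mer-m8", "7mer-A1"), k,
                                  replace = TRUE))
  }))
  sim <- simulate_utrs(20, 300, fams, plant, rng_seed = 63)
  m <- count_matrix(sim$utrs, fams)
  truth <- table(factor(sim$sites$family_id, rownames(m)),
                 factor(sim$sites$gene_id, colnames(m)))
  expect_true(all(unclass(m) == truth))
  expect_equal(sum(m), nrow(plant))
})

test_that("expression generator plants the exact top-N intersection", {
  e0 <- simulate_expression(60, n_top = 20, n_expressed_in_both = 0,
                            rng_seed = 71)
  expect_equal(length(top_n_entities(e0$table_a, e0$table_b, 20)), 0L)
  e <- simulate_expression(200, n_top = 100, n_expressed_in_both = 46,
                           rng_seed = 72)
  expect_equal(length(e$shared), 46L)
  expect_error(simulate_expression(100, n_top = 80, n_expressed_in_both = 10),
               "n_entities")
})

test_that("AP generator produces the analytic piecewise waveform truth", {
  s <- simulate_ap_trace(n_beats = 4, baseline = 1, amplitude = 1,
                         upstroke_duration = 0, plateau_duration = 200,
                         repolarization_duration = 200, beat_interval = 1000,
                         sampling_interval = 2)
  expect_equal(unique(s$truth$apd90_ms), 380)
  expect_equal(s$truth$rr_ms, c(NA, 1000, 1000, 1000))
  expect_equal(max(s$trace$signal), 2)
  expect_equal(min(s$trace$signal), 1)
  # zero beats: flat baseline, empty truth
  s0 <- simulate_ap_trace(n_beats = 0, baseline = 1.5)
  expect_equal(nrow(s0$truth), 0L)
  expect_true(all(s0$trace$signal == 1.5))
  # coarse sampling cannot represent the upstroke
  expect_error(simulate_ap_trace(upstroke_duration = 5, sampling_interval = 10),
               "too coarse")
  # waveform must fit in the beat interval
  expect_error(simulate_ap_trace(beat_interval = 300, plateau_duration = 200,
                                 repolarization_duration = 200),
               "beat_interval")
})

test_that("force generator applies the hard refractory response rule", {
  sched <- build_schedule(start_ms = 600, stop_ms = 300, step_ms = 300,
                          block_duration_s = 4)
  sim <- simulate_force_trace(400, sched, rng_seed = 81)
  st <- sim$trace$stimuli
  # block 1 (600 ms > RP): S2 evokes a twitch; force near S2 peak is high
  s2a <- st$time_ms[st$block == 1 & st$type == "S2"][1]
  i <- which.min(abs(sim$trace$time - (s2a + 66)))
  expect_gt(sim$trace$force[i], 0.5)
  # block 2 (300 ms <= RP): S2 suppressed; force at the would-be peak is
  # only the S1 tail
  s2b <- st$time_ms[st$block == 2 & st$type == "S2"][1]
  j <- which.min(abs(sim$trace$time - (s2b + 66)))
  expect_lt(sim$trace$force[j], 0.4)
  # graded mode evokes a scaled twitch
  simg <- simulate_force_trace(400, sched, refractory_response_fraction = 0.5)
  expect_gt(simg$trace$force[j], 0.2)
})

test_that("DE generator labels targets and ties FDR to effect size", {
  d0 <- simulate_de_table(100, 0, rng_seed = 91)
  expect_false(any(d0$is_target))
  d <- simulate_de_table(500, 50, target_shift = -1, sd_log2fc = 0.2,
                         rng_seed = 92)
  expect_equal(sum(d$is_target), 50L)
  expect_lt(median(d$table$fdr[d$is_target]),
            median(d$table$fdr[!d$is_target]))
  expect_true(all(d$table$fdr >= 0 & d$table$fdr <= 1))
  expect_false(anyDuplicated(d$table$gene_id) > 0)
})

test_that("reporter generator centers treated ratios at the planted factor", {
  cells <- simulate_reporter_cells(200, repression_factor = 0.5, cv = 0,
                                   rng_seed = 95)
  expect_equal(unique(cells$treated$gfp / cells$treated$rfp), 0.5)
  expect_equal(unique(cells$control$gfp / cells$control$rfp), 1)
  noisy <- simulate_reporter_cells(500, repression_factor = 0.7, cv = 0.1,
                                   rng_seed = 96)
  r <- mean(noisy$treated$gfp / noisy$treated$rfp) /
    mean(noisy$control$gfp / noisy$control$rfp)
  expect_lt(abs(r - 0.7), 0.05)
})
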