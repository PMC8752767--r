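test_that("seed extraction returns miRNA positions 2-8 and enforces length", {
  expect_equal(seed_of("UAAUGCCCCUAAAAAUCCUUAU"), "AAUGCCC")
  expect_equal(seed_of("UAAUGCCC"), "AAUGCCC")   # minimal 8-nt input
  expect_warning(s <- seed_of("TAATGCCC"), "converting T to U")
  expect_equal(s, "AAUGCCC")
  expect_error(seed_of("UAAUGCC"), "at least 8 nt")
})

test_that("canonical site strings follow the 8mer/7mer-m8/7mer-A1 taxonomy", {
  expect_equal(site_sequences("AAUGCCC"),
               c("8mer" = "GGGCAUUA", "7mer-m8" = "GGGCAUU",
                 "7mer-A1" = "GGCAUUA"))
  expect_equal(site_sequences("AAAAAAA"),
               c("8mer" = "UUUUUUUA", "7mer-m8" = "UUUUUUU",
                 "7mer-A1" = "UUUUUUA"))
  for (i in 1:25) {
    s <- random_seed()
    ss <- site_sequences(s)
    expect_identical(substr(ss[["8mer"]], 1, 7), ss[["7mer-m8"]])
    expect_identical(unname(site_sequences(s, "DNA")),
                     chartr("U", "T", unname(ss)))
  }
})

test_that("scanner reports maximal sites with 8mer subsumption", {
  hit <- scan_sites("AAGGGCATTAAA", "AAUGCCC", "g", "F")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$site_type, "8mer")
  expect_equal(c(hit$start, hit$end), c(2L, 10L))
  expect_equal(nrow(scan_sites("CCCCCCC", "AAUGCCC")), 0L)
  # N never matches
  expect_equal(nrow(scan_sites("AAGGGCNTTAAA", "AAUGCCC")), 0L)
})

test_that("scanner equals the naive all-window oracle on random inputs", {
  set.seed(421)
  for (i in 1:300) {
    utr <- random_utr(sample(30:150, 1))
    seed <- random_seed()
    got <- scan_sites(utr, seed)
    exp <- oracle_scan(utr, seed)
    expect_identical(site_key(got), site_key(exp))
  }
  # and on a long UTR enriched for matches of one family
  seed <- "AAUGCCC"
  ss <- chartr("U", "T", unname(site_sequences(seed)))
  utr <- paste(sample(c(rep(ss, 40),
                        replicate(400, random_utr(9)))), collapse = "")
  expect_identical(site_key(scan_sites(utr, seed)),
                   site_key(oracle_scan(utr, seed)))
})

test_that("no reported 7mer lies inside a same-family 8mer; counts conserve", {
  set.seed(77)
  for (i in 1:60) {
    utr <- random_utr(500)
    seed <- random_seed()
    d <- scan_sites(utr, seed, "g", "F")
    p8 <- d$start[d$site_type == "8mer"]
    for (p in p8) {
      expect_false(any(d$site_type == "7mer-m8" & d$start == p))
      expect_false(any(d$site_type == "7mer-A1" & d$start == p + 1))
    }
    expect_true(all(d$end - d$start == ifelse(d$site_type == "8mer", 8L, 7L)))
  }
})

test_that("scanning is invariant to DNA vs RNA input alphabets", {
  set.seed(5)
  for (i in 1:40) {
    utr <- random_utr(200)
    seed <- random_seed()
    a <- scan_sites(utr, seed)
    b <- scan_sites(chartr("T", "U", utr), seed)
    expect_identical(site_key(a), site_key(b))
  }
})

test_that("dual-dataset top-N gating is an intersection with deterministic ties", {
  ta <- data.frame(id = c("a", "b", "c", "d"), abundance = c(9, 8, 7, 6))
  tb <- data.frame(id = c("a", "b", "c", "d"), abundance = c(1, 2, 9, 8))
  expect_equal(top_n_entities(ta, tb, 2), character(0))  # disjoint tops
  expect_equal(top_n_entities(ta, ta, 2), c("a", "b"))   # identity
  # tie at the boundary resolved lexicographically
  tt <- data.frame(id = c("z", "y", "x"), abundance = c(5, 1, 1))
  expect_equal(top_n_entities(tt, tt, 2), c("x", "z"))
  e <- simulate_expression(200, n_top = 100, n_expressed_in_both = 46,
                           rng_seed = 11)
  expect_equal(top_n_entities(e$table_a, e$table_b, 100), e$shared)
})

test_that("expression gate uses a strict abundance threshold", {
  tb <- data.frame(id = c("g1", "g2", "g3"), abundance = c(1.0, 1.01, 0))
  expect_equal(filter_expressed_genes(tb, 1), "g2")
  expect_equal(filter_expressed_genes(data.frame(id = "g", abundance = 0), 1),
               character(0))
})

test_that("count matrix matches planted ground truth and ranking sorts by burden", {
  fams <- random_seed_families(4, rng_seed = 31)
  plant <- data.frame(
    gene_id = c("g001", "g001", "g002", "g003", "g003", "g003"),
    family_id = c("F01", "F01", "F02", "F01", "F03", "F03"),
    site_type = c("8mer", "7mer-m8", "7mer-A1", "8mer", "8mer", "7mer-m8"))
  sim <- simulate_utrs(4, 250, fams, plant, rng_seed = 32)
  m <- count_matrix(sim$utrs, fams)
  want <- with(sim$sites, table(factor(family_id, rownames(m)),
                                factor(gene_id, colnames(m))))
  expect_equal(unclass(m), unclass(m) * 0 + as.integer(want),
               ignore_attr = TRUE)
  expect_equal(sum(m), nrow(attr(m, "sites")))  # count conservation
  rk <- rank_families(m)
  expect_equal(rk$family_id[1:2], c("F01", "F03"))
  expect_equal(rk$n_sites, sort(rk$n_sites, decreasing = TRUE))
  expect_equal(rk$n_sites[rk$family_id == "F01"], 3L)
  expect_true(all(strsplit(rk$genes[1], ";")[[1]] %in% c("g001", "g003")))
})

test_that("zero planted sites give a zero matrix; row sums add across genes", {
  fams <- random_seed_families(3, rng_seed = 41)
  sim <- simulate_utrs(5, 120, fams, rng_seed = 42)
  m <- count_matrix(sim$utrs, fams)
  expect_true(all(m == 0L))
  expect_equal(nrow(sim$sites), 0L)
  rk <- rank_families(m)
  expect_equal(rk$family_id, sort(fams$family_id))  # lexicographic tie-break
})

test_that("conservation filter needs annotations and restricts counts", {
  fams <- random_seed_families(2, rng_seed = 51)
  plant <- data.frame(gene_id = c("g001", "g002"),
                      family_id = c("F01", "F02"),
                      site_type = c("8mer", "8mer"))
  sim <- simulate_utrs(2, 150, fams, plant, rng_seed = 52)
  expect_error(count_matrix(sim$utrs, fams, conservation_filter = TRUE),
               "annotation")
  ann <- sim$sites[1, c("gene_id", "family_id", "start")]
  m <- count_matrix(sim$utrs, fams, conservation_filter = TRUE,
                    conserved_sites = ann)
  expect_equal(sum(m), 1L)
})

test_that("longest UTR is scanned when a gene has several transcripts", {
  fams <- data.frame(family_id = "F01", seed = "AAUGCCC")
  utrs <- c(gA = "AAGGGCATTAAA", gA = "CCCCCC", gB = "TTTTTTTT")
  expect_message(m <- count_matrix(utrs, fams), "longest")
  expect_equal(as.integer(m["F01", "gA"]), 1L)
})

test_that("miRNAs sharing a heptamer collapse into one seed family", {
  mir <- data.frame(id = c("mir-b", "mir-a", "mir-c"),
                    sequence = c("UAAUGCCCCUA", "CAAUGCCCGGG", "UGGGGGGGGA"))
  f <- seed_families(mir)
  expect_equal(nrow(f), 2L)
  expect_equal(f$members[f$seed == "AAUGCCC"], "mir-a;mir-b")
  expect_equal(f$family_id[f$seed == "AAUGCCC"], "mir-a")
})
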