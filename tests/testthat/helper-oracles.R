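# Independent oracles and small fixture builders, implemented without the
# package's own scanning / statistics code paths.

# reverse complement via chartr + rev, independent of Biostrings
oracle_rc <- function(s, alphabet = "DNA") {
  comp <- if (alphabet == "DNA") chartr("ACGTU", "TGCAA", s)
          else chartr("ACGTU", "UGCAU", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# canonical site strings for a seed, DNA alphabet
oracle_site_strings <- function(seed_rna) {
  seed_dna <- chartr("U", "T", seed_rna)
  m8 <- oracle_rc(seed_dna)
  list(`8mer` = paste0(m8, "A"),
       `7mer-m8` = m8,
       `7mer-A1` = paste0(oracle_rc(substr(seed_dna, 1, 6)), "A"))
}

# naive all-window scanner applying the documented hierarchy: an 8mer match
# subsumes its internal 7mer-m8 (same start) and 7mer-A1 (start + 1); if
# the two 7mer strings coincide, a window is reported once as 7mer-m8.
# Returns data.frame(site_type, start) with 0-based starts, sorted.
oracle_scan <- function(utr_dna, seed_rna) {
  ss <- oracle_site_strings(seed_rna)
  n <- nchar(utr_dna)
  win_match <- function(pat) {
    k <- nchar(pat)
    if (n < k) return(integer(0))
    starts <- 0:(n - k)
    starts[vapply(starts, function(i)
      substr(utr_dna, i + 1, i + k) == pat, logical(1))]
  }
  p8 <- win_match(ss$`8mer`)
  pm8 <- setdiff(win_match(ss$`7mer-m8`), p8)
  pa1 <- if (ss$`7mer-A1` == ss$`7mer-m8`) integer(0)
         else setdiff(win_match(ss$`7mer-A1`), p8 + 1)
  out <- data.frame(
    site_type = rep(c("8mer", "7mer-m8", "7mer-A1"),
                    c(length(p8), length(pm8), length(pa1))),
    start = c(p8, pm8, pa1))
  out[order(out$start, out$site_type), , drop = FALSE]
}

# exhaustive hypergeometric upper tail from binomial coefficients only
oracle_hyper_p <- function(overlap, term_size, target_size, universe_size) {
  j <- overlap:min(term_size, target_size)
  sum(choose(term_size, j) * choose(universe_size - term_size, target_size - j)) /
    choose(universe_size, target_size)
}

random_utr <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
random_seed <- function() paste(sample(c("A", "C", "G", "U"), 7,
                                       replace = TRUE), collapse = "")

# canonical comparison form of a site table
site_key <- function(d) sort(paste(d$site_type, d$start))

# construct a trace from raw vectors (internal constructor)
as_trace_for_test <- function(time, signal) cardiomiR:::as_trace(time, signal)
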