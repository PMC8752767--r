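# Internal helpers shared across modules.

#' @importFrom stats quantile median mad phyper p.adjust wilcox.test ks.test
#'   rnorm runif pnorm lm predict coef sd t.test
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. A conversion triggers a warning so that
#' silently mixed alphabets are visible in logs.
#' @param x character vector of sequences
#' @param warn warn when T -> U conversion happens
#' @return character vector over {A,C,G,U,N}
#' @keywords internal
normalize_rna <- function(x, warn = TRUE) {
  x <- toupper(x)
  if (any(grepl("T", x, fixed = TRUE))) {
    if (warn) warning("DNA alphabet detected; converting T to U", call. = FALSE)
    x <- gsub("T", "U", x, fixed = TRUE)
  }
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) stop("invalid nucleotide characters in sequence(s): ",
                     paste(head(which(bad), 3), collapse = ", "))
  x
}

# DNA normalization (U -> T), used internally for UTR scanning.
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("invalid nucleotide characters in sequence(s): ",
                     paste(head(which(bad), 3), collapse = ", "))
  x
}

# All (possibly overlapping) 1-based start positions of `pattern` in `subject`.
# Plain fixed-string matching; N in the subject never matches.
str_find_all <- function(subject, pattern) {
  n <- nchar(subject); k <- nchar(pattern)
  if (n < k) return(integer(0))
  m <- Biostrings::matchPattern(pattern, subject, fixed = TRUE)
  Biostrings::start(m)
}

# Centered moving average with shrinking windows at the edges.
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || length(x) < 3L) return(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
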