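# Readers and writers for the package's external formats: FASTA for miRNA
# and UTR sequences (via Biostrings), headered TSV for expression / DE /
# intensity / site tables, CSV for traces and stimulus timestamps.

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA file
#' @return data.frame(id, sequence) in the RNA alphabet (T converted to U
#'   with a warning)
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(id = names(x),
             sequence = normalize_rna(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read 3' UTR sequences from FASTA
#'
#' @param path FASTA file
#' @return named character vector (gene id -> DNA sequence)
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(normalize_dna(as.character(x)), names(x))
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read / write a headered TSV table
#'
#' @param path file path
#' @return data.frame
#' @export
read_tsv_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @param x data.frame to write
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV (time_ms plus one or two channels)
#'
#' One channel column yields the signal directly; two yield the
#' channel-1 / channel-2 ratio via [ratio_trace()].
#'
#' @param path CSV with a `time_ms` column and 1-2 channel columns
#' @return a `ratio_trace`
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"time_ms" %in% names(d)) stop("trace CSV needs a 'time_ms' column")
  ch <- setdiff(names(d), "time_ms")
  if (length(ch) == 1L) as_trace(d$time_ms, d[[ch]], metadata = list(channel = ch))
  else if (length(ch) == 2L)
    ratio_trace(d[[ch[1L]]], d[[ch[2L]]], d$time_ms,
                metadata = list(numerator = ch[1L], denominator = ch[2L]))
  else stop("trace CSV must carry one or two channel columns")
}

#' Write a trace to CSV
#'
#' @param trace `ratio_trace` or `force_trace`
#' @param path output CSV
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "force_trace"))
    utils::write.csv(data.frame(time_ms = trace$time, force_mN = trace$force),
                     path, row.names = FALSE)
  else
    utils::write.csv(data.frame(time_ms = trace$time, signal = trace$signal),
                     path, row.names = FALSE)
  invisible(path)
}

#' Read a force trace plus its stimulus timestamps
#'
#' @param trace_path CSV with columns time_ms, force_mN
#' @param stimuli_path CSV with columns time_ms, type, block
#' @return a `force_trace`
#' @export
read_force_csv <- function(trace_path, stimuli_path) {
  d <- utils::read.csv(trace_path)
  s <- utils::read.csv(stimuli_path)
  force_trace(d$time_ms, d$force_mN, s)
}

#' Read term-to-gene membership from a two-column TSV
#'
#' @param path TSV with columns term, gene
#' @return named list of gene-id vectors
#' @export
read_term_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("term", "gene") %in% names(d)))
  split(d$gene, d$term)
}
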