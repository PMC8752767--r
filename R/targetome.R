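# Canonical miRNA seed-site scanning and binding-site counting over a gene
# panel (the "channelome" screen): seed extraction, the three canonical site
# types (8mer, 7mer-m8, 7mer-A1), subsumption-aware scanning, expression
# gating, the family-by-gene count matrix and the site-burden ranking.

#' Canonical seed of a mature miRNA
#'
#' The seed is the heptamer at positions 2--8 (1-based) of the mature miRNA,
#' the region that nucleates canonical target pairing. Sequences given in the
#' DNA alphabet are converted to RNA with a warning.
#'
#' @param sequence mature miRNA sequence, 5'->3', length >= 8
#' @return 7-nt RNA seed string
#' @examples
#' seed_of("UAAUGCCCCUAAAAAUCCUUAU")  # "AAUGCCC"
#' @export
seed_of <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("'sequence' must be a single string")
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) < 8L)
    stop("mature miRNA must be at least 8 nt to define a seed (got ",
         nchar(sequence), ")")
  substr(sequence, 2L, 8L)
}

#' Target-strand sequences of the three canonical site types
#'
#' For a 7-nt seed (miRNA positions 2--8) the canonical sites on the target
#' (UTR) strand are: 7mer-m8, the reverse complement of the full seed; 8mer,
#' the 7mer-m8 followed by an A (opposite miRNA position 1, required to be a
#' literal A); and 7mer-A1, the reverse complement of seed positions 1--6
#' (miRNA nt 2--7) followed by an A.
#'
#' @param seed 7-nt seed (RNA or DNA letters)
#' @param alphabet alphabet of the returned site strings
#' @return named character vector with elements `8mer`, `7mer-m8`, `7mer-A1`
#' @examples
#' site_sequences("AAUGCCC")
#' @export
site_sequences <- function(seed, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  seed <- normalize_rna(seed, warn = FALSE)
  if (nchar(seed) != 7L) stop("seed must be exactly 7 nt")
  if (grepl("N", seed, fixed = TRUE)) stop("seed must not contain N")
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  m8  <- rc(seed)
  out <- c("8mer" = paste0(m8, "A"),
           "7mer-m8" = m8,
           "7mer-A1" = paste0(rc(substr(seed, 1L, 6L)), "A"))
  if (alphabet == "DNA") out <- chartr("U", "T", out)
  out
}

# Core scanner on a DNA-normalized subject string. Returns 0-based half-open
# coordinates. Subsumption: an 8mer match at p is one site; the 7mer-m8 that
# starts at p and the 7mer-A1 that starts at p+1 are its internal windows and
# are suppressed. If the 7mer-m8 and 7mer-A1 strings coincide (degenerate
# seeds such as poly-U), a matching window is reported once, as 7mer-m8.
.scan_core <- function(subject_dna, seed) {
  sites <- site_sequences(seed, alphabet = "DNA")
  p8 <- str_find_all(subject_dna, sites[["8mer"]]) - 1L
  pm8 <- str_find_all(subject_dna, sites[["7mer-m8"]]) - 1L
  pm8 <- setdiff(pm8, p8)
  if (sites[["7mer-A1"]] == sites[["7mer-m8"]]) {
    pa1 <- integer(0)
  } else {
    pa1 <- str_find_all(subject_dna, sites[["7mer-A1"]]) - 1L
    pa1 <- setdiff(pa1, p8 + 1L)
  }
  out <- data.frame(
    site_type = rep(c("8mer", "7mer-m8", "7mer-A1"),
                    times = c(length(p8), length(pm8), length(pa1))),
    start = c(p8, pm8, pa1),
    stringsAsFactors = FALSE)
  out$end <- out$start + ifelse(out$site_type == "8mer", 8L, 7L)
  out[order(out$start, out$site_type), , drop = FALSE]
}

#' Scan a 3' UTR for canonical seed sites of one family
#'
#' Reports all maximal canonical sites without double counting: a window
#' matching the 8mer is reported once as an 8mer and its internal 7mer
#' windows are suppressed; all remaining 7mer-m8 and 7mer-A1 matches are
#' reported, including mutually overlapping ones. DNA and RNA input yield
#' identical sites; N never matches. Coordinates are 0-based, half-open on
#' the supplied UTR sequence.
#'
#' @param utr_seq UTR sequence (DNA or RNA)
#' @param seed 7-nt seed of the family
#' @param gene_id,family_id identifiers copied into the output
#' @return data.frame with columns gene_id, family_id, site_type, start,
#'   end, conserved (NA unless annotated downstream), sorted by start
#' @examples
#' scan_sites("AAGGGCATTAAA", "AAUGCCC", gene_id = "KCNQ1", family_id = "F1")
#' @export
scan_sites <- function(utr_seq, seed, gene_id = NA_character_,
                       family_id = NA_character_) {
  if (length(utr_seq) != 1L || !nzchar(utr_seq)) stop("UTR must be a non-empty string")
  hits <- .scan_core(normalize_dna(utr_seq), seed)
  data.frame(gene_id = rep(gene_id, nrow(hits)),
             family_id = rep(family_id, nrow(hits)),
             hits,
             conserved = rep(NA, nrow(hits)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group mature miRNAs into seed families
#'
#' miRNAs sharing the positions 2--8 heptamer form one family with a common
#' canonical target spectrum. The family is named after its lexicographically
#' first member.
#'
#' @param mirnas data.frame with columns `id` and `sequence`
#' @return data.frame with columns family_id, seed, members
#'   (semicolon-joined ids), n_members
#' @export
seed_families <- function(mirnas) {
  stopifnot(is.data.frame(mirnas), all(c("id", "sequence") %in% names(mirnas)))
  seeds <- vapply(mirnas$sequence, seed_of, character(1), USE.NAMES = FALSE)
  fam <- split(mirnas$id, seeds)
  out <- data.frame(
    family_id = vapply(fam, function(m) sort(m)[1L], character(1)),
    seed = names(fam),
    members = vapply(fam, function(m) paste(sort(m), collapse = ";"), character(1)),
    n_members = lengths(fam),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$family_id), , drop = FALSE]
}

#' Entities highly expressed in two datasets
#'
#' Intersection of the top-`n` ids by abundance taken independently in each
#' table, the dual-dataset expression gate used to keep only miRNAs abundant
#' in both cultured myocytes and adult myocardium. Ties at the boundary are
#' broken by abundance, then lexicographically by id, so the result is
#' deterministic.
#'
#' @param table_a,table_b data.frames with columns `id` and `abundance`
#' @param n size of each top list
#' @return character vector of ids (sorted)
#' @export
top_n_entities <- function(table_a, table_b, n = 100L) {
  stopifnot(n >= 1L)
  topn <- function(tb) {
    stopifnot(is.data.frame(tb), all(c("id", "abundance") %in% names(tb)),
              nrow(tb) > 0L)
    ord <- order(-tb$abundance, tb$id)
    tb$id[ord][seq_len(min(n, nrow(tb)))]
  }
  sort(intersect(topn(table_a), topn(table_b)))
}

#' Genes expressed above an abundance threshold
#'
#' Strict inequality: a gene at exactly the threshold is excluded (TPM > 1
#' by default).
#'
#' @param expr_table data.frame with columns `id` and `abundance` (TPM-like)
#' @param threshold abundance cutoff
#' @return character vector of gene ids
#' @export
filter_expressed_genes <- function(expr_table, threshold = 1) {
  stopifnot(is.data.frame(expr_table),
            all(c("id", "abundance") %in% names(expr_table)))
  sort(expr_table$id[expr_table$abundance > threshold])
}

#' Binding-site count matrix over a gene panel
#'
#' Scans every (family, gene) pair and tabulates canonical site counts, the
#' object behind the site-burden ranking of candidate miRNAs. When several
#' UTR sequences share a gene id (transcript isoforms) the longest is
#' scanned, with a message. With `conservation_filter = TRUE` only sites
#' matching the supplied annotation (gene_id, family_id, start) are counted.
#'
#' @param utrs named character vector of UTR sequences (names = gene ids) or
#'   data.frame with columns gene_id, sequence
#' @param families data.frame with columns family_id, seed
#' @param conservation_filter restrict to annotated conserved sites
#' @param conserved_sites annotation data.frame (gene_id, family_id, start);
#'   required when the filter is on
#' @return integer matrix (families x genes) of class `binding_site_matrix`,
#'   with the full site table in `attr(, "sites")`
#' @export
count_matrix <- function(utrs, families, conservation_filter = FALSE,
                         conserved_sites = NULL) {
  if (is.data.frame(utrs)) {
    stopifnot(all(c("gene_id", "sequence") %in% names(utrs)))
    utrs <- stats::setNames(utrs$sequence, utrs$gene_id)
  }
  stopifnot(length(utrs) > 0L, !is.null(names(utrs)))
  stopifnot(is.data.frame(families), nrow(families) > 0L,
            all(c("family_id", "seed") %in% names(families)))
  if (conservation_filter && is.null(conserved_sites))
    stop("conservation_filter = TRUE requires a 'conserved_sites' annotation")
  if (anyDuplicated(names(utrs))) {
    keep <- tapply(seq_along(utrs), names(utrs),
                   function(i) i[which.max(nchar(utrs[i]))])
    message("multiple UTRs for ", sum(table(names(utrs)) > 1L),
            " gene(s); scanning the longest per gene")
    utrs <- utrs[unlist(keep)]
  }
  genes <- sort(names(utrs))
  utrs <- vapply(utrs[genes], normalize_dna, character(1))
  fams <- families[order(families$family_id), , drop = FALSE]

  site_list <- vector("list", nrow(fams) * length(genes))
  k <- 0L
  for (f in seq_len(nrow(fams))) {
    for (g in seq_along(genes)) {
      k <- k + 1L
      s <- scan_sites(utrs[[g]], fams$seed[f],
                      gene_id = genes[g], family_id = fams$family_id[f])
      if (nrow(s)) site_list[[k]] <- s
    }
  }
  sites <- do.call(rbind, site_list)
  if (is.null(sites))
    sites <- data.frame(gene_id = character(0), family_id = character(0),
                        site_type = character(0), start = integer(0),
                        end = integer(0), conserved = logical(0))
  if (conservation_filter) {
    stopifnot(all(c("gene_id", "family_id", "start") %in% names(conserved_sites)))
    key <- function(d) paste(d$gene_id, d$family_id, d$start, sep = "\r")
    keep <- key(sites) %in% key(conserved_sites)
    sites$conserved <- keep
    sites <- sites[keep, , drop = FALSE]
  }
  m <- matrix(0L, nrow = nrow(fams), ncol = length(genes),
              dimnames = list(fams$family_id, genes))
  if (nrow(sites)) {
    tab <- table(factor(sites$family_id, levels = fams$family_id),
                 factor(sites$gene_id, levels = genes))
    m[] <- as.integer(tab)
  }
  structure(m, sites = sites, scan_params = list(
    conservation_filter = conservation_filter),
    class = c("binding_site_matrix", "matrix", "array"))
}

#' @export
print.binding_site_matrix <- function(x, ...) {
  cat("Binding-site count matrix:", nrow(x), "seed families x",
      ncol(x), "genes;", sum(x), "sites total\n")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Rank seed families by total binding-site burden
#'
#' Orders families by their total canonical site count across the gene
#' panel (descending; ties broken lexicographically by family id) and lists
#' the genes each family targets -- the prioritization that surfaces the
#' top channelome-targeting miRNA candidates.
#'
#' @param matrix a `binding_site_matrix`
#' @return data.frame with columns family_id, n_sites, n_genes, genes
#'   (semicolon-joined ids of genes with >= 1 site)
#' @export
rank_families <- function(matrix) {
  stopifnot(inherits(matrix, "binding_site_matrix") ||
              (is.matrix(matrix) && !is.null(dimnames(matrix))))
  totals <- rowSums(matrix)
  ord <- order(-totals, rownames(matrix))
  genes <- apply(matrix[ord, , drop = FALSE], 1L,
                 function(r) paste(colnames(matrix)[r > 0], collapse = ";"))
  data.frame(family_id = rownames(matrix)[ord],
             n_sites = as.integer(totals[ord]),
             n_genes = as.integer(rowSums(matrix[ord, , drop = FALSE] > 0)),
             genes = unname(genes),
             row.names = NULL, stringsAsFactors = FALSE)
}
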