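# Targetome statistics: hypergeometric (Fisher exact) over-representation of
# a target set in disease/GO terms, the differential-expression filters and
# reciprocal-regulation set logic, and the target-vs-background fold-change
# shift test.

#' Fisher exact over-representation of a target set in term gene sets
#'
#' For each term the 2x2 table (in-target x in-term over the universe) is
#' tested one-sided for over-representation; the p-value is the upper tail
#' of the hypergeometric distribution, identical to the one-sided Fisher
#' exact test. The per-term `contribution` is overlap / term size, the
#' bubble-size quantity of a classic disease-enrichment plot. No multiple-
#' testing correction is applied by default (raw p against 0.05); set
#' `bh = TRUE` for a Benjamini-Hochberg column, which is logged.
#'
#' @param targets character vector of target gene ids
#' @param terms named list of character vectors (term -> member genes)
#' @param universe character vector, the enrichment universe; targets and
#'   terms must be subsets
#' @param bh add a BH-adjusted p-value column
#' @return data.frame of class `enrichment_result`, one row per term,
#'   sorted by ascending p-value, with columns term, overlap, term_size,
#'   target_size, universe_size, p_value, contribution
#' @examples
#' fisher_enrichment(paste0("g", 1:4),
#'                   list(t1 = paste0("g", 1:5)),
#'                   paste0("g", 1:10))
#' @export
fisher_enrichment <- function(targets, terms, universe, bh = FALSE) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  targets <- unique(targets)
  if (!all(targets %in% universe)) stop("targets must be a subset of the universe")
  if (is.null(names(terms)) || !is.list(terms))
    stop("'terms' must be a named list of gene-id vectors")
  res <- lapply(names(terms), function(nm) {
    term <- unique(terms[[nm]])
    if (!all(term %in% universe))
      stop("term '", nm, "' is not a subset of the universe")
    ov <- length(intersect(targets, term))
    data.frame(term = nm, overlap = ov, term_size = length(term),
               target_size = length(targets), universe_size = length(universe),
               p_value = phyper(ov - 1L, length(term),
                                length(universe) - length(term),
                                length(targets), lower.tail = FALSE),
               contribution = if (length(term)) ov / length(term) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (bh) {
    message("applying Benjamini-Hochberg correction across ", nrow(out), " terms")
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  }
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter a differential-expression table by effect size and FDR
#'
#' Retains genes with FDR below `max_fdr` and an expression change larger
#' than `min_change` on the linear scale. Upregulation always means
#' FC > 1 + min_change. For downregulation two conventions exist and the
#' choice is logged: `"linear"` (default) requires FC < 1 - min_change
#' (e.g. < 0.70 for a 30% change); `"reciprocal"` requires
#' FC < 1 / (1 + min_change) (~0.769), the mirror of the up threshold in
#' log space.
#'
#' @param table data.frame with columns gene_id, log2fc, fdr
#' @param min_change minimum fractional expression change (0.30 = 30%)
#' @param max_fdr FDR cutoff (strict inequality)
#' @param direction which tail(s) to keep
#' @param down_mapping mapping of `min_change` to the down threshold
#' @return character vector of retained gene ids
#' @export
de_filter <- function(table, min_change = 0.30, max_fdr = 0.05,
                      direction = c("both", "down", "up"),
                      down_mapping = c("linear", "reciprocal")) {
  direction <- match.arg(direction)
  down_mapping <- match.arg(down_mapping)
  stopifnot(is.data.frame(table),
            all(c("gene_id", "log2fc", "fdr") %in% names(table)))
  if (anyDuplicated(table$gene_id)) stop("gene ids must be unique")
  if (nrow(table) == 0L) return(character(0))
  fc <- 2^table$log2fc
  up_thr <- 1 + min_change
  down_thr <- if (down_mapping == "linear") 1 - min_change else 1 / (1 + min_change)
  message(sprintf("de_filter: fdr < %g, up FC > %.4g, down FC < %.4g (%s mapping)",
                  max_fdr, up_thr, down_thr, down_mapping))
  sig <- table$fdr < max_fdr
  keep <- switch(direction,
                 up   = sig & fc > up_thr,
                 down = sig & fc < down_thr,
                 both = sig & (fc > up_thr | fc < down_thr))
  sort(table$gene_id[keep])
}

#' Reciprocally regulated genes
#'
#' Intersection of the genes repressed under miRNA gain with the genes
#' derepressed under miRNA inhibition -- the reciprocal-regulation signature
#' of direct or coherent targets.
#'
#' @param down_in_mimic,up_in_antimir character vectors of gene ids
#' @return sorted character vector
#' @export
reciprocal_set <- function(down_in_mimic, up_in_antimir) {
  sort(intersect(down_in_mimic, up_in_antimir))
}

#' Fold-change shift of predicted targets against the transcriptome
#'
#' Compares the log2 fold-change distribution of predicted target genes
#' against all remaining genes in the table. The primary statistic is the
#' two-sided Wilcoxon rank-sum; the Kolmogorov-Smirnov statistic is
#' reported alongside as a distribution-shape check. The effect size is the
#' difference of group medians (target - background) in log2 units.
#'
#' @param table data.frame with columns gene_id, log2fc (an `fdr` column is
#'   ignored here)
#' @param target_ids character vector of predicted target gene ids
#' @return object of class `shift_test`: list with statistic (rank-sum W),
#'   p_value, ks_statistic, ks_p_value, median_shift, n_target, n_background
#' @export
target_shift_test <- function(table, target_ids) {
  stopifnot(is.data.frame(table),
            all(c("gene_id", "log2fc") %in% names(table)))
  is_t <- table$gene_id %in% target_ids
  x <- table$log2fc[is_t]      # targets
  y <- table$log2fc[!is_t]     # background
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 target and >= 2 background genes present in the table")
  w <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                    exact = FALSE, correct = TRUE))
  # all-tied input has zero rank variance: the statistic sits at its null
  # center and carries no evidence
  if (is.nan(w$p.value)) w$p.value <- 1
  ks <- suppressWarnings(ks.test(x, y))
  structure(list(statistic = unname(w$statistic),
                 p_value = w$p.value,
                 ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value,
                 median_shift = median(x) - median(y),
                 n_target = length(x), n_background = length(y)),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat("Target fold-change shift test (rank-sum)\n")
  cat(sprintf("  targets: %d  background: %d\n", x$n_target, x$n_background))
  cat(sprintf("  W = %.4g, p = %.3g;  KS D = %.3f (p = %.3g)\n",
              x$statistic, x$p_value, x$ks_statistic, x$ks_p_value))
  cat(sprintf("  median log2FC shift (target - background): %+.3f\n",
              x$median_shift))
  invisible(x)
}
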