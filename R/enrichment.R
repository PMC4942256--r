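#' One-sided Fisher's exact enrichment p-value
#'
#' Tests enrichment of inactivating insertions in the selected pool against
#' the control library on the 2x2 table
#' \code{[[k_sel, n_sel - k_sel], [k_ctrl, n_ctrl - k_ctrl]]}. The one-sided
#' (enrichment) p-value equals the hypergeometric upper-tail sum
#' \eqn{P(X \ge k_{sel})} with \eqn{X \sim}
#' Hypergeometric(\eqn{k_{sel}+k_{ctrl}} successes,
#' \eqn{(n_{sel}-k_{sel})+(n_{ctrl}-k_{ctrl})} failures, \eqn{n_{sel}} draws).
#' Zero cells need no pseudocounts. Vectorized over the counts.
#'
#' @param k_sel inactivating sites for the gene in the selected pool.
#' @param n_sel total inactivating sites in the selected pool.
#' @param k_ctrl inactivating sites for the gene in the control library.
#' @param n_ctrl total inactivating sites in the control library.
#' @param alternative \code{"greater"} (enrichment, default) or
#'   \code{"two.sided"} (delegates to \code{stats::fisher.test}).
#' @return p-value(s) in (0, 1].
#' @examples
#' fisher_enrichment(5, 10, 1, 100)
#' @export
fisher_enrichment <- function(k_sel, n_sel, k_ctrl, n_ctrl,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(k_sel < 0 | k_ctrl < 0 | n_sel <= 0 | n_ctrl <= 0))
    stop("counts must be non-negative and totals positive", call. = FALSE)
  if (any(k_sel > n_sel | k_ctrl > n_ctrl))
    stop("k cannot exceed its total n", call. = FALSE)
  if (alternative == "greater") {
    stats::phyper(k_sel - 1,
                  m = k_sel + k_ctrl,
                  n = (n_sel - k_sel) + (n_ctrl - k_ctrl),
                  k = n_sel, lower.tail = FALSE)
  } else {
    mapply(function(a, ns, c, nc) {
      stats::fisher.test(matrix(c(a, ns - a, c, nc - c), 2, byrow = TRUE),
                         alternative = "two.sided")$p.value
    }, k_sel, n_sel, k_ctrl, n_ctrl)
  }
}

#' Per-gene enrichment of a selected screen pool over a control library
#'
#' The central statistic of the screen: for every annotated gene, the number
#' of unique inactivating insertion sites in the drug-selected pool is
#' compared against the same count in the unselected control library by
#' Fisher's exact test, with the genome-wide totals of inactivating sites as
#' the table margins. Raw p-values are reported (as in the screen read-out);
#' a Benjamini-Hochberg column is appended for convenience.
#'
#' @param selected per-gene counts (from \code{\link{per_gene_counts}}) for
#'   the selected pool.
#' @param control per-gene counts for the control library.
#' @param alternative passed to \code{\link{fisher_enrichment}}.
#' @return an object of class \code{screen_enrichment}: a list with
#'   \code{table} (one row per gene: gene_id, chrom, start,
#'   chrom_order_index, k_selected, k_control, total_reads, bubble_n,
#'   p_value, bh_q, in chromosomal order), \code{n_selected_total},
#'   \code{n_control_total}, and the call. Methods: \code{print},
#'   \code{summary}, \code{plot}, \code{as.data.frame}.
#' @export
screen_enrichment <- function(selected, control,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!setequal(selected$gene_id, control$gene_id) ||
      nrow(selected) != nrow(control)) {
    d1 <- setdiff(selected$gene_id, control$gene_id)
    d2 <- setdiff(control$gene_id, selected$gene_id)
    stop("selected and control tables cover different genes: ",
         "only in selected: {", paste(d1, collapse = ", "), "}; ",
         "only in control: {", paste(d2, collapse = ", "), "}",
         call. = FALSE)
  }
  control <- control[match(selected$gene_id, control$gene_id), , drop = FALSE]
  n_sel <- sum(selected$n_inactivating_sites)
  n_ctrl <- sum(control$n_inactivating_sites)
  if (n_sel == 0 || n_ctrl == 0)
    stop("a pool with zero inactivating sites cannot be tested",
         call. = FALSE)
  p <- fisher_enrichment(selected$n_inactivating_sites, n_sel,
                         control$n_inactivating_sites, n_ctrl,
                         alternative = alternative)
  tab <- data.frame(
    gene_id = selected$gene_id,
    chrom = selected$chrom,
    start = selected$start,
    k_selected = selected$n_inactivating_sites,
    k_control = control$n_inactivating_sites,
    total_reads = selected$total_reads,
    bubble_n = selected$n_inactivating_sites,
    p_value = p,
    bh_q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$start, tab$gene_id), , drop = FALSE]
  tab$chrom_order_index <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, n_selected_total = n_sel,
                 n_control_total = n_ctrl, alternative = alternative,
                 call = match.call()),
            class = "screen_enrichment")
}

#' Drop genes below a read-support threshold from a result table
#'
#' Genes with fewer than \code{min_total_reads} sequencing reads in the
#' selected pool are removed from display (strictly "less than": a gene at
#' exactly the threshold is kept). Default 10; use 50 for the
#' validation-screen presentation.
#'
#' @param results a \code{screen_enrichment} object or its table.
#' @param min_total_reads threshold on selected-pool reads.
#' @return same class as the input, filtered.
#' @export
display_filter <- function(results, min_total_reads = 10L) {
  if (inherits(results, "screen_enrichment")) {
    results$table <- display_filter(results$table, min_total_reads)
    return(results)
  }
  out <- results[results$total_reads >= min_total_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

ranked_table <- function(x) {
  tab <- x$table
  tab[order(tab$p_value, tab$gene_id), , drop = FALSE]  # lexicographic ties
}

#' @export
print.screen_enrichment <- function(x, ...) {
  cat("Gene-trap screen enrichment (Fisher's exact test, ",
      x$alternative, ")\n", sep = "")
  cat(sprintf("  %d genes; %d inactivating sites selected vs %d control\n",
              nrow(x$table), x$n_selected_total, x$n_control_total))
  top <- utils::head(ranked_table(x), 5L)
  cat("  top genes:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-10s k_sel = %3d  k_ctrl = %3d  p = %.3g\n",
                top$gene_id[i], top$k_selected[i], top$k_control[i],
                top$p_value[i]))
  invisible(x)
}

#' @export
summary.screen_enrichment <- function(object, alpha = 0.05, ...) {
  tab <- ranked_table(object)
  structure(list(table = tab, alpha = alpha,
                 n_significant = sum(tab$p_value < alpha),
                 n_genes = nrow(tab),
                 n_selected_total = object$n_selected_total,
                 n_control_total = object$n_control_total),
            class = "summary.screen_enrichment")
}

#' @export
print.summary.screen_enrichment <- function(x, ...) {
  cat(sprintf("%d of %d genes with p < %g (raw Fisher p)\n",
              x$n_significant, x$n_genes, x$alpha))
  print(utils::head(x$table[, c("gene_id", "k_selected", "k_control",
                                "total_reads", "p_value", "bh_q")], 10L),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.screen_enrichment <- function(x, ...) x$table

#' Bubble plot of screen enrichment
#'
#' Genes on the x axis in chromosomal order, \eqn{-\log_{10} p} on the y
#' axis, bubble diameter proportional to the number of unique inactivating
#' sites in the selected pool.
#'
#' @param x a \code{screen_enrichment} object.
#' @param min_total_reads display filter applied before plotting.
#' @param label_top label this many top genes.
#' @param ... passed to \code{plot}.
#' @export
plot.screen_enrichment <- function(x, min_total_reads = 10L, label_top = 3L,
                                   ...) {
  tab <- display_filter(x$table, min_total_reads)
  if (!nrow(tab)) stop("no genes pass the display filter", call. = FALSE)
  y <- -log10(tab$p_value)
  cex <- 0.5 + 2 * sqrt(tab$bubble_n / max(1, max(tab$bubble_n)))
  graphics::plot(tab$chrom_order_index, y, cex = cex, pch = 21,
                 bg = "steelblue",
                 xlab = "genes in chromosomal order",
                 ylab = expression(-log[10] ~ p), ...)
  if (label_top > 0) {
    top <- utils::head(order(tab$p_value, tab$gene_id), label_top)
    graphics::text(tab$chrom_order_index[top], y[top], tab$gene_id[top],
                   pos = 3, cex = 0.8)
  }
  invisible(x)
}

#' Compare screen count totals against published reference values
#'
#' Validation surface for externally produced site tables (e.g. journal
#' source-data files): recomputes the number of unique insertion sites, the
#' number classified as inactivating, and optionally the unique inactivating
#' sites in one gene of interest, and compares them to reference totals. The
#' default references are the published control-library totals of the screen
#' this package models (142,800 unique insertions, 38,628 inactivating).
#'
#' @param sites site table (chrom, pos, orientation, read_count).
#' @param models exon table for classification.
#' @param reference named numeric: \code{unique_insertions},
#'   \code{inactivating_insertions}.
#' @param gene optional gene id whose inactivating-site count to report.
#' @param gene_reference optional reference count for \code{gene}.
#' @return data.frame: quantity, observed, reference, match.
#' @export
validate_screen_counts <- function(sites, models,
                                   reference = c(unique_insertions = 142800,
                                                 inactivating_insertions = 38628),
                                   gene = NULL, gene_reference = NULL) {
  cl <- classify_insertions(sites, models)
  inact_idx <- unique(cl$site_index[cl$inactivating])
  obs <- c(unique_insertions = nrow(sites),
           inactivating_insertions = length(inact_idx))
  ref <- c(reference["unique_insertions"],
           reference["inactivating_insertions"])
  out <- data.frame(quantity = names(obs), observed = as.numeric(obs),
                    reference = as.numeric(ref),
                    stringsAsFactors = FALSE)
  if (!is.null(gene)) {
    k <- sum(cl$inactivating & cl$gene_id == gene)
    out <- rbind(out, data.frame(
      quantity = paste0("inactivating_sites_", gene), observed = k,
      reference = if (is.null(gene_reference)) NA_real_ else gene_reference,
      stringsAsFactors = FALSE))
  }
  out$match <- !is.na(out$reference) & out$observed == out$reference
  out
}

#' @rdname write_sites_tsv
#' @param results a \code{screen_enrichment} object or its table.
#' @export
write_enrichment_tsv <- function(results, path) {
  tab <- if (inherits(results, "screen_enrichment")) results$table else results
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
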