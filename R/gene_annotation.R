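#' Gene spans from an exon table
#'
#' @param models exon table (gene_id, chrom, strand, start, end; 0-based
#'   half-open).
#' @return one row per gene: gene_id, chrom, strand, start, end, ordered by
#'   chromosome then start (chromosomal location order).
#' @export
gene_spans <- function(models) {
  sp <- do.call(rbind, lapply(split(models, models$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  sp <- sp[order(sp$chrom, sp$start, sp$gene_id), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' Classify insertion sites against gene models
#'
#' Gene-trap insertions disrupt a gene when they land in an exon (any
#' orientation) or in an intron with the provirus in the gene's
#' transcriptional (sense) orientation; antisense intronic insertions are
#' spliced around and typically leave the gene functional. Each site is
#' evaluated independently against every gene whose span contains it, so a
#' site inside two overlapping genes yields two rows.
#'
#' @param sites data.frame with chrom, pos (0-based), orientation.
#' @param models exon table (gene_id, chrom, strand, start, end).
#' @param exon_requires_sense also require sense orientation for exonic
#'   insertions (default \code{FALSE}: exonic insertions count in any
#'   orientation).
#' @return data.frame: site_index (row of \code{sites}), gene_id,
#'   inactivating (logical). Sites outside all gene spans contribute no rows.
#' @export
classify_insertions <- function(sites, models, exon_requires_sense = FALSE) {
  empty <- data.frame(site_index = integer(0), gene_id = character(0),
                      inactivating = logical(0), stringsAsFactors = FALSE)
  if (!nrow(sites) || !nrow(models)) return(empty)
  missing_chrom <- setdiff(unique(sites$chrom), unique(models$chrom))
  if (length(missing_chrom))
    warning("site chromosome(s) absent from annotation: ",
            paste(missing_chrom, collapse = ", "), call. = FALSE)

  lvls <- union(unique(sites$chrom), unique(models$chrom))
  pts <- GenomicRanges::GRanges(
    factor(sites$chrom, levels = lvls),
    IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  spans <- gene_spans(models)
  span_gr <- GenomicRanges::GRanges(
    factor(spans$chrom, levels = lvls),
    IRanges::IRanges(spans$start + 1L, spans$end))
  exon_gr <- GenomicRanges::GRanges(
    factor(models$chrom, levels = lvls),
    IRanges::IRanges(models$start + 1L, models$end))

  h <- GenomicRanges::findOverlaps(pts, span_gr)
  if (!length(h)) return(empty)
  si <- S4Vectors::queryHits(h)
  gi <- S4Vectors::subjectHits(h)

  eh <- GenomicRanges::findOverlaps(pts, exon_gr)
  exonic_keys <- unique(paste(S4Vectors::queryHits(eh),
                              models$gene_id[S4Vectors::subjectHits(eh)]))
  exonic <- paste(si, spans$gene_id[gi]) %in% exonic_keys
  sense <- sites$orientation[si] == spans$strand[gi]
  inact <- (exonic & (sense | !exon_requires_sense)) | (!exonic & sense)

  out <- data.frame(site_index = si, gene_id = spans$gene_id[gi],
                    inactivating = inact, stringsAsFactors = FALSE)
  out[order(out$site_index, out$gene_id), , drop = FALSE]
}

#' @rdname classify_insertions
#' @param site a single-row site (list or data.frame with chrom, pos,
#'   orientation).
#' @return for \code{classify_insertion}: data.frame gene_id, inactivating
#'   (zero rows for an intergenic site).
#' @export
classify_insertion <- function(site, models, exon_requires_sense = FALSE) {
  s <- as.data.frame(site, stringsAsFactors = FALSE)
  cl <- classify_insertions(s, models, exon_requires_sense)
  cl[, c("gene_id", "inactivating"), drop = FALSE]
}

#' Per-gene counts of inactivating insertions
#'
#' Counts, for every gene in the annotation (zero-count genes included), the
#' unique inactivating insertion sites and the total sequencing reads over
#' those sites. Rows are ordered by chromosomal location.
#'
#' @param sites site table (chrom, pos, orientation, read_count; a missing
#'   read_count column counts each site as one read).
#' @param models exon table.
#' @param exon_requires_sense see \code{\link{classify_insertions}}.
#' @return data.frame: gene_id, chrom, start, n_inactivating_sites,
#'   total_reads.
#' @export
per_gene_counts <- function(sites, models, exon_requires_sense = FALSE) {
  spans <- gene_spans(models)
  out <- data.frame(gene_id = spans$gene_id, chrom = spans$chrom,
                    start = spans$start,
                    n_inactivating_sites = 0L, total_reads = 0L,
                    stringsAsFactors = FALSE)
  if (!nrow(sites)) return(out)
  rc <- if ("read_count" %in% names(sites)) sites$read_count
        else rep(1L, nrow(sites))
  cl <- classify_insertions(sites, models, exon_requires_sense)
  cl <- cl[cl$inactivating, , drop = FALSE]
  if (!nrow(cl)) return(out)
  n_sites <- table(cl$gene_id)
  reads <- tapply(rc[cl$site_index], cl$gene_id, sum)
  i <- match(names(n_sites), out$gene_id)
  out$n_inactivating_sites[i] <- as.integer(n_sites)
  out$total_reads[i] <- as.integer(reads[names(n_sites)])
  out
}

#' Read gene models from a GTF subset or BED12 file
#'
#' GTF coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention at this boundary; only \code{exon} features are used
#' and genes are identified by the \code{gene_id} attribute. BED12 block
#' structures are expanded to exons.
#'
#' @param path annotation file.
#' @return exon table (gene_id, chrom, strand, start, end).
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  out <- data.frame(gene_id = gr$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_gene_models_gtf
#' @export
read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  rows <- lapply(seq_along(gr), function(i) {
    blk <- gr$blocks[[i]]
    chrom_start <- GenomicRanges::start(gr)[i] - 1L  # back to 0-based
    data.frame(gene_id = gr$name[i],
               chrom = as.character(GenomicRanges::seqnames(gr))[i],
               strand = as.character(GenomicRanges::strand(gr))[i],
               start = chrom_start + BiocGenerics::start(blk) - 1L,
               end = chrom_start + BiocGenerics::end(blk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname write_sites_tsv
#' @param counts per-gene count table.
#' @export
write_gene_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
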