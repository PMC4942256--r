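#' Generate a synthetic genome and gene models
#'
#' Draws i.i.d. uniform A/C/G/T chromosome sequences and places \code{n_genes}
#' non-overlapping gene models on them. Each gene has a number of exons drawn
#' from \code{config$exons_per_gene}, exon and intron lengths drawn from the
#' configured ranges (introns >= 50 bp), and a random strand. All coordinates
#' are 0-based half-open.
#'
#' @param config a \code{\link{screen_sim_config}}.
#' @param allow_overlap place genes independently of each other instead of
#'   packing them without overlap.
#' @return a list with \code{genome} (a named \code{DNAStringSet}) and
#'   \code{genes} (a data.frame with one row per exon: \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{start}, \code{end}).
#' @export
generate_genome <- function(config, allow_overlap = FALSE) {
  validate_config(config)
  with_stream(config$seed, "genome", {
    chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
    seqs <- vapply(chrom_names, function(nm) {
      paste(sample(c("A", "C", "G", "T"), config$chromosome_length,
                   replace = TRUE), collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chrom_names

    genes <- if (config$n_genes > 0L) {
      place_genes(config, chrom_names, allow_overlap)
    } else {
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)
    }
    list(genome = genome, genes = genes)
  })
}

# Draw gene structures, assign chromosomes, and pack genes left to right with
# random gaps (stick-breaking over the free space). Errors out if the drawn
# spans cannot fit, which is the explicit infeasible-packing contract.
place_genes <- function(config, chrom_names, allow_overlap) {
  ng <- config$n_genes
  # sample.int-based range draw: safe for degenerate ranges where sample()
  # would fall into its 1:n convenience behaviour
  draw <- function(rng, n) rng[1] + sample.int(rng[2] - rng[1] + 1L, n,
                                               replace = TRUE) - 1L
  n_ex <- draw(config$exons_per_gene, ng)
  structures <- lapply(n_ex, function(k) {
    ex <- draw(config$exon_length, k)
    intr <- if (k > 1) draw(config$intron_length, k - 1) else integer(0)
    # exon starts relative to the gene start
    rel_start <- cumsum(c(0L, ex[-k] + intr))
    cbind(start = rel_start, end = rel_start + ex)
  })
  spans <- vapply(structures, function(s) s[nrow(s), "end"], numeric(1))
  chrom <- sample(chrom_names, ng, replace = TRUE)
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  starts <- integer(ng)
  for (cn in chrom_names) {
    idx <- which(chrom == cn)
    if (!length(idx)) next
    if (allow_overlap) {
      max_start <- config$chromosome_length - spans[idx]
      if (any(max_start < 0))
        stop("infeasible packing: a gene span exceeds the chromosome length",
             call. = FALSE)
      starts[idx] <- vapply(max_start, function(m) sample.int(m + 1L, 1L) - 1L,
                            integer(1))
    } else {
      free <- config$chromosome_length - sum(spans[idx])
      if (free < 0)
        stop("infeasible packing: gene spans exceed chromosome length on ", cn,
             call. = FALSE)
      w <- stats::runif(length(idx) + 1L)
      gaps <- floor(free * w / sum(w))
      ord <- sample(idx)  # random left-to-right order
      pos <- 0L
      for (j in seq_along(ord)) {
        pos <- pos + gaps[j]
        starts[ord[j]] <- as.integer(pos)
        pos <- pos + spans[ord[j]]
      }
    }
  }

  rows <- lapply(seq_len(ng), function(i) {
    s <- structures[[i]]
    data.frame(gene_id = sprintf("gene%03d", i), chrom = chrom[i],
               strand = strand[i],
               start = as.integer(starts[i] + s[, "start"]),
               end = as.integer(starts[i] + s[, "end"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Inject a repeated segment into a synthetic genome
#'
#' Copies one randomly chosen segment to additional loci so that reads
#' originating from any copy map to multiple places and are discarded by the
#' unique-placement rule. Used to exercise multi-mapper handling.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param width repeat length in bp.
#' @param n_copies total number of copies (the original plus
#'   \code{n_copies - 1} pasted duplicates).
#' @param seed integer seed.
#' @return a list with the modified \code{genome} and a data.frame \code{loci}
#'   (chrom, start, end; 0-based half-open) of all copies.
#' @export
inject_repeat <- function(genome, width, n_copies = 2L, seed = 1L) {
  stopifnot(n_copies >= 2L, width >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lens <- Biostrings::width(genome)
  pick <- function() {
    ci <- sample.int(length(genome), 1L)
    list(chrom = names(genome)[ci],
         start = sample.int(lens[ci] - width + 1L, 1L) - 1L)
  }
  src <- pick()
  seg <- as.character(Biostrings::subseq(genome[[src$chrom]],
                                         src$start + 1L, src$start + width))
  loci <- data.frame(chrom = src$chrom, start = src$start,
                     end = src$start + width, stringsAsFactors = FALSE)
  seqs <- as.character(genome)
  for (i in seq_len(n_copies - 1L)) {
    dst <- pick()
    substr(seqs[[dst$chrom]], dst$start + 1L, dst$start + width) <- seg
    loci <- rbind(loci, data.frame(chrom = dst$chrom, start = dst$start,
                                   end = dst$start + width,
                                   stringsAsFactors = FALSE))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  list(genome = out, loci = loci)
}

#' Simulate the retroviral insertion library
#'
#' Draws \code{n_insertions} independent integration events, one per haploid
#' cell: positions uniform over the genome, orientations a fair coin. The
#' position is the 0-based first genomic base 3' of the proviral LTR junction;
#' the orientation is the proviral transcriptional direction on the genome.
#'
#' @param genome a named \code{DNAStringSet} (from \code{generate_genome}).
#' @param config a \code{\link{screen_sim_config}}.
#' @return data.frame with columns \code{cell_id}, \code{chrom}, \code{pos},
#'   \code{orientation}.
#' @export
simulate_insertions <- function(genome, config) {
  if (config$n_insertions <= 0L)
    stop("n_insertions must be positive", call. = FALSE)
  with_stream(config$seed, "insertions", {
    lens <- Biostrings::width(genome)
    ci <- sample.int(length(genome), config$n_insertions, replace = TRUE,
                     prob = lens / sum(lens))
    pos <- floor(stats::runif(config$n_insertions) * lens[ci])
    data.frame(cell_id = seq_len(config$n_insertions),
               chrom = names(genome)[ci],
               pos = as.integer(pos),
               orientation = sample(c("+", "-"), config$n_insertions,
                                    replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Apply drug selection to the insertion library
#'
#' Each cell survives independently: with probability
#' \code{p_survive_resistant} if its insertion inactivates any resistance gene
#' (exonic in any orientation, or intronic in the gene's sense orientation),
#' otherwise with \code{p_survive_background}.
#'
#' @param events insertion events from \code{\link{simulate_insertions}}.
#' @param gene_models exon table from \code{\link{generate_genome}}.
#' @param config a \code{\link{screen_sim_config}} naming
#'   \code{resistance_genes}.
#' @return the surviving subset of \code{events}.
#' @export
apply_selection <- function(events, gene_models, config) {
  res <- config$resistance_genes
  unknown <- setdiff(res, unique(gene_models$gene_id))
  if (length(unknown))
    stop("unknown resistance gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  inact_res <- rep(FALSE, nrow(events))
  if (length(res)) {
    hits <- classify_insertions(events, gene_models)
    hits <- hits[hits$inactivating & hits$gene_id %in% res, , drop = FALSE]
    inact_res[unique(hits$site_index)] <- TRUE
  }
  p <- ifelse(inact_res, config$p_survive_resistant,
              config$p_survive_background)
  with_stream(config$seed, "selection", {
    keep <- stats::runif(nrow(events)) < p
    events[keep, , drop = FALSE]
  })
}

#' Synthesize inverse-PCR sequencing reads for surviving insertions
#'
#' For each event a read count is drawn from the shifted negative-binomial
#' depth model (support >= 1). Each read starts at the insertion position and
#' runs in the proviral orientation (reverse-complemented for orientation
#' \code{-}), is truncated at the end of the first TTAA (MseI) or CATG
#' (NlaIII) occurrence if one falls within the read length, and is emitted at
#' a constant Phred quality. Events that cannot yield a read of at least 20
#' genomic bases -- because the insertion sits too close to a chromosome end,
#' or because a restriction site truncates the fragment below 20 bp -- are
#' recorded in the truth table with a skip flag and produce no reads.
#'
#' @param events surviving insertion events.
#' @param genome a named \code{DNAStringSet}.
#' @param config a \code{\link{screen_sim_config}}.
#' @return list with \code{reads} (data.frame: read_id, sequence) and
#'   \code{truth} (data.frame: read_id, cell_id, chrom, pos, orientation,
#'   skip); skipped events carry \code{NA} read_id and \code{skip = TRUE}.
#' @export
synthesize_reads <- function(events, genome, config) {
  if (!nrow(events)) stop("no surviving events to sequence", call. = FALSE)
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  L <- config$read_length

  avail <- ifelse(events$orientation == "+",
                  lens[events$chrom] - events$pos,
                  events$pos + 1L)
  frag <- character(nrow(events))
  for (i in which(avail >= 20L)) {
    n <- min(L, avail[i])
    if (events$orientation[i] == "+") {
      frag[i] <- as.character(Biostrings::subseq(
        genome[[events$chrom[i]]], events$pos[i] + 1L, events$pos[i] + n))
    } else {
      s <- as.character(Biostrings::subseq(
        genome[[events$chrom[i]]], events$pos[i] + 2L - n, events$pos[i] + 1L))
      frag[i] <- revcomp(s)
    }
  }
  frag <- trim_at_restriction_site(frag)
  skip <- nchar(frag) < 20L  # near-telomere or truncated below mappable size
  if (any(skip))
    warning(sum(skip), " event(s) cannot yield >= 20 genomic bases ",
            "(chromosome end or restriction-site truncation); skipped",
            call. = FALSE)
  keep <- which(!skip)
  frag <- frag[keep]
  if (nzchar(config$ltr_prefix)) frag <- paste0(config$ltr_prefix, frag)

  with_stream(config$seed, "reads", {
    counts <- 1L + stats::rnbinom(length(keep), size = config$depth_dispersion,
                                  mu = config$depth_mean - 1)
    read_event <- rep(keep, counts)
    read_seq <- rep(frag, counts)
    read_id <- sprintf("read%07d", seq_along(read_event))
    reads <- data.frame(read_id = read_id, sequence = read_seq,
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = read_id,
                        cell_id = events$cell_id[read_event],
                        chrom = events$chrom[read_event],
                        pos = events$pos[read_event],
                        orientation = events$orientation[read_event],
                        skip = FALSE, stringsAsFactors = FALSE)
    if (any(skip)) {
      truth <- rbind(truth, data.frame(
        read_id = NA_character_,
        cell_id = events$cell_id[skip],
        chrom = events$chrom[skip],
        pos = events$pos[skip],
        orientation = events$orientation[skip],
        skip = TRUE, stringsAsFactors = FALSE))
    }
    list(reads = reads, truth = truth)
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write simulator outputs to standard formats
#'
#' @param genome named \code{DNAStringSet}.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param genes exon table (gene_id, chrom, strand, start, end; 0-based
#'   half-open), written as a GTF subset with \code{gene} and \code{exon}
#'   features.
#' @export
write_gene_models_gtf <- function(genes, path) {
  spans <- gene_spans(genes)
  gr_gene <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand, type = "gene", gene_id = spans$gene_id)
  gr_exon <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand, type = "exon", gene_id = genes$gene_id)
  gr <- c(gr_gene, gr_exon)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_gene_models_bed12 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  grl <- GenomicRanges::split(gr, genes$gene_id)
  bed <- rtracklayer::asBED(grl)
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param reads data.frame (read_id, sequence); written as Phred-33 FASTQ with
#'   constant quality "I".
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param truth truth table from \code{\link{synthesize_reads}}.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
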