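cfg_small <- screen_sim_config(n_chromosomes = 2, chromosome_length = 1e5,
                               n_genes = 20, exons_per_gene = 3L,
                               n_insertions = 1000, seed = 1)

test_that("genome generation is seeded, in bounds, and structurally valid", {
  g1 <- generate_genome(cfg_small)
  g2 <- generate_genome(cfg_small)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)

  expect_length(g1$genome, 2L)
  expect_true(all(Biostrings::width(g1$genome) == 1e5))
  expect_false(any(grepl("[^ACGT]", as.character(g1$genome))))

  genes <- g1$genes
  expect_length(unique(genes$gene_id), 20L)
  for (g in split(genes, genes$gene_id)) {
    expect_equal(nrow(g), 3L)                       # exons_per_gene
    expect_true(all(diff(g$start) > 0))             # sorted
    expect_true(all(g$start[-1] - g$end[-3] >= 50)) # introns >= 50 bp
    expect_true(all(g$start >= 0 & g$end <= 1e5))
  }
  # non-overlapping gene spans within each chromosome
  sp <- gene_spans(genes)
  for (cn in unique(sp$chrom)) {
    s <- sp[sp$chrom == cn, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("infeasible gene packing raises an explicit error", {
  expect_error(
    screen_sim_config(n_chromosomes = 1, chromosome_length = 5000,
                      n_genes = 50, exons_per_gene = 3L, n_insertions = 10),
    "genome length")
  # feasible on average, but this seed lands both genes on one chromosome
  cfg <- screen_sim_config(n_chromosomes = 2, chromosome_length = 6000,
                           n_genes = 2, exons_per_gene = 1L,
                           exon_length = 3500L, n_insertions = 10, seed = 1)
  expect_error(generate_genome(cfg), "infeasible packing")
})

test_that("insertion libraries are uniform, fair-coin oriented and seeded", {
  cfg <- screen_sim_config(n_chromosomes = 2, chromosome_length = 1e5,
                           n_genes = 0, n_insertions = 10000, seed = 5)
  gen <- generate_genome(cfg)
  ev <- simulate_insertions(gen$genome, cfg)
  expect_equal(nrow(ev), 10000L)
  expect_true(all(ev$pos >= 0 & ev$pos < 1e5))
  expect_true(all(ev$chrom %in% names(gen$genome)))
  expect_identical(ev, simulate_insertions(gen$genome, cfg))

  # orientation is a fair coin: two-sided exact binomial at alpha = 0.001
  bt <- binom.test(sum(ev$orientation == "+"), nrow(ev), p = 0.5)
  expect_gt(bt$p.value, 0.001)

  cfg_bad <- cfg
  cfg_bad$n_insertions <- 0L
  expect_error(simulate_insertions(gen$genome, cfg_bad), "positive")
})

test_that("selection with degenerate probabilities is exact", {
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 1e5,
                           n_genes = 10, exons_per_gene = 3L,
                           n_insertions = 2000,
                           p_survive_resistant = 1, p_survive_background = 0,
                           seed = 11)
  gen <- generate_genome(cfg)
  ev <- simulate_insertions(gen$genome, cfg)
  cfg$resistance_genes <- "gene004"
  surv <- apply_selection(ev, gen$genes, cfg)

  cl <- classify_insertions(ev, gen$genes)
  expected <- sort(unique(
    cl$site_index[cl$inactivating & cl$gene_id == "gene004"]))
  expect_identical(surv$cell_id, ev$cell_id[expected])

  # empty resistance set and zero background survival -> nobody survives
  cfg$resistance_genes <- character(0)
  expect_equal(nrow(apply_selection(ev, gen$genes, cfg)), 0L)

  cfg$resistance_genes <- "no_such_gene"
  expect_error(apply_selection(ev, gen$genes, cfg), "unknown resistance gene")
})

test_that("genotype-independent selection preserves library composition", {
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 1e5,
                           n_genes = 10, exons_per_gene = 3L,
                           n_insertions = 20000,
                           resistance_genes = "gene001",
                           p_survive_resistant = 0.5,
                           p_survive_background = 0.5, seed = 13)
  gen <- generate_genome(cfg)
  ev <- simulate_insertions(gen$genome, cfg)
  surv <- apply_selection(ev, gen$genes, cfg)

  lib_counts <- per_gene_counts(ev, gen$genes)
  surv_counts <- per_gene_counts(surv, gen$genes)
  keep <- lib_counts$n_inactivating_sites > 0
  # chi-square goodness of fit of the survivor gene composition against the
  # library proportions
  ct <- suppressWarnings(stats::chisq.test(
    surv_counts$n_inactivating_sites[keep],
    p = lib_counts$n_inactivating_sites[keep] /
      sum(lib_counts$n_inactivating_sites[keep])))
  expect_gt(ct$p.value, 0.001)
})

test_that("read synthesis follows the truncation rule on planted motifs", {
  # motif-free backbone with a TTAA planted 20 bases after position 10
  s <- motif_free(200)
  substr(s, 31, 34) <- "TTAA"
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 1000,
                           n_genes = 0, n_insertions = 10, seed = 1)

  ev <- data.frame(cell_id = 1:2, chrom = "chr1", pos = c(10L, 100L),
                   orientation = "+", stringsAsFactors = FALSE)
  out <- synthesize_reads(ev, genome, cfg)
  seq_by_cell <- function(cell) {
    ids <- out$truth$read_id[out$truth$cell_id == cell & !out$truth$skip]
    unique(out$reads$sequence[out$reads$read_id %in% ids])
  }
  # TTAA starts 20 bases downstream -> trimmed through the site, length 24
  expect_identical(seq_by_cell(1), substr(s, 11, 34))
  expect_equal(nchar(seq_by_cell(1)), 24L)
  # no motif within 50 bases -> exact 50-mer
  expect_identical(seq_by_cell(2), substr(s, 101, 150))

  # reverse orientation reads the reverse complement ending at the junction
  ev_m <- data.frame(cell_id = 1L, chrom = "chr1", pos = 150L,
                     orientation = "-", stringsAsFactors = FALSE)
  out_m <- synthesize_reads(ev_m, genome, cfg)
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 102, 151))))
  expect_identical(unique(out_m$reads$sequence), expected)

  # conservation: reads emitted == truth rows for non-skipped events
  expect_equal(nrow(out$reads), sum(!out$truth$skip))
  expect_true(all(out$reads$read_id %in% out$truth$read_id))
})

test_that("events that cannot yield 20 mappable bases are skip-flagged", {
  s <- motif_free(200)
  substr(s, 61, 64) <- "CATG"  # truncates a read starting at pos 55 to 10 bp
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 1000,
                           n_genes = 0, n_insertions = 10, seed = 1)
  ev <- data.frame(cell_id = 1:3, chrom = "chr1",
                   pos = c(195L,   # 5 bases to the chromosome end
                           54L,    # CATG 6 bases in: truncated to 10 bp
                           100L),  # clean
                   orientation = "+", stringsAsFactors = FALSE)
  expect_warning(out <- synthesize_reads(ev, genome, cfg), "skipped")
  expect_identical(out$truth$cell_id[out$truth$skip], c(1L, 2L))
  expect_true(all(is.na(out$truth$read_id[out$truth$skip])))
  expect_true(all(out$truth$cell_id[!out$truth$skip] == 3L))
})

test_that("read counts follow the shifted depth model and are conserved", {
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 5e4,
                           n_genes = 0, n_insertions = 2000, seed = 21)
  gen <- generate_genome(cfg)
  ev <- simulate_insertions(gen$genome, cfg)
  out <- suppressWarnings(synthesize_reads(ev, gen$genome, cfg))
  counts <- table(out$truth$cell_id[!out$truth$skip])
  expect_true(all(counts >= 1))                  # support >= 1
  expect_gt(mean(counts), 15); expect_lt(mean(counts), 25)
  expect_equal(nrow(out$reads), sum(counts))     # conservation
  # deterministic re-run
  out2 <- suppressWarnings(synthesize_reads(ev, gen$genome, cfg))
  expect_identical(out$reads, out2$reads)
})

test_that("simulator output round-trips through standard formats", {
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 3e4,
                           n_genes = 5, exons_per_gene = c(2L, 3L),
                           n_insertions = 100, seed = 2)
  gen <- generate_genome(cfg)
  ev <- simulate_insertions(gen$genome, cfg)
  out <- suppressWarnings(synthesize_reads(ev, gen$genome, cfg))

  fa <- tempfile(fileext = ".fa"); fq <- tempfile(fileext = ".fq")
  gtf <- tempfile(fileext = ".gtf"); bed <- tempfile(fileext = ".bed")
  write_genome_fasta(gen$genome, fa)
  write_reads_fastq(out$reads, fq)
  write_gene_models_gtf(gen$genes, gtf)
  write_gene_models_bed12(gen$genes, bed)

  expect_identical(as.character(Biostrings::readDNAStringSet(fa)),
                   as.character(gen$genome))
  rd <- read_reads(fq)
  expect_identical(rd$sequence, out$reads$sequence)

  key <- function(m) m[order(m$gene_id, m$start),
                       c("gene_id", "chrom", "strand", "start", "end")]
  expect_equal(key(read_gene_models_gtf(gtf)), key(gen$genes),
               ignore_attr = TRUE)
  expect_equal(key(read_gene_models_bed12(bed)), key(gen$genes),
               ignore_attr = TRUE)
})
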