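#' Configuration for a synthetic haploid gene-trap screen
#'
#' Bundles every knob of the screen simulator: the synthetic genome geometry,
#' the insertion library size, the genotype-dependent survival probabilities
#' applied during drug selection, and the per-site sequencing depth model.
#' Defaults describe the simulated study conditions used throughout the
#' package: a 2 x 1 Mb genome carrying 100 genes, a library of 50,000
#' independent single-integration cells, strong selection
#' (\code{p_survive_resistant} = 0.9 vs \code{p_survive_background} = 0.001)
#' and 50 bp single-end reads.
#'
#' @param n_chromosomes number of chromosomes in the synthetic genome.
#' @param chromosome_length length of each chromosome in bp.
#' @param n_genes number of genes to place on the genome.
#' @param exons_per_gene integer range (length-2 vector) of exons per gene;
#'   a single value is recycled to a degenerate range.
#' @param n_insertions number of independent insertion events (one per
#'   simulated haploid cell).
#' @param resistance_genes character vector of gene ids whose inactivation
#'   confers drug resistance.
#' @param p_survive_resistant survival probability under selection for a cell
#'   whose insertion inactivates a resistance gene.
#' @param p_survive_background survival probability for every other cell.
#' @param read_length sequencing read length in bp (>= 20).
#' @param depth_mean mean of the per-site read-count distribution.
#' @param depth_dispersion negative-binomial size (dispersion) parameter of
#'   the depth model; counts are drawn as 1 + NB(mu = depth_mean - 1, size =
#'   depth_dispersion) so every emitted site has at least one read.
#' @param exon_length integer range of exon lengths in bp.
#' @param intron_length integer range of intron lengths in bp (minimum 50).
#' @param multi_integration allow more than one integration per cell
#'   (default off: the screen works with clonal single-integration lines).
#' @param ltr_prefix optional fixed vector-sequence prefix prepended to every
#'   synthesized read, to exercise vector-trimming code paths; \code{""}
#'   (none) by default.
#' @param seed integer seed; every simulator operation is bit-reproducible
#'   given the config.
#'
#' @return an object of class \code{screen_sim_config} (a validated list).
#' @examples
#' cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 1e5,
#'                          n_genes = 10, n_insertions = 500, seed = 1)
#' @export
screen_sim_config <- function(n_chromosomes = 2,
                              chromosome_length = 1e6,
                              n_genes = 100,
                              exons_per_gene = c(2L, 6L),
                              n_insertions = 50000,
                              resistance_genes = character(0),
                              p_survive_resistant = 0.9,
                              p_survive_background = 0.001,
                              read_length = 50L,
                              depth_mean = 20,
                              depth_dispersion = 0.5,
                              exon_length = c(100L, 300L),
                              intron_length = c(200L, 2000L),
                              multi_integration = FALSE,
                              ltr_prefix = "",
                              seed = 1L) {
  if (length(exons_per_gene) == 1L) exons_per_gene <- rep(exons_per_gene, 2L)
  if (length(exon_length) == 1L) exon_length <- rep(exon_length, 2L)
  if (length(intron_length) == 1L) intron_length <- rep(intron_length, 2L)
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    n_insertions = as.integer(n_insertions),
    resistance_genes = as.character(resistance_genes),
    p_survive_resistant = p_survive_resistant,
    p_survive_background = p_survive_background,
    read_length = as.integer(read_length),
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    multi_integration = isTRUE(multi_integration),
    ltr_prefix = toupper(as.character(ltr_prefix)),
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1L,
    cfg$chromosome_length >= 1000L,
    cfg$n_genes >= 0L,
    length(cfg$exons_per_gene) == 2L,
    cfg$exons_per_gene[1] >= 1L,
    cfg$exons_per_gene[1] <= cfg$exons_per_gene[2]
  )
  if (cfg$p_survive_resistant < 0 || cfg$p_survive_resistant > 1 ||
      cfg$p_survive_background < 0 || cfg$p_survive_background > 1)
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$read_length < 20L)
    stop("read_length must be at least 20 bp", call. = FALSE)
  if (cfg$intron_length[1] < 50L)
    stop("introns must be at least 50 bp", call. = FALSE)
  if (cfg$depth_mean <= 1 || cfg$depth_dispersion <= 0)
    stop("depth model needs depth_mean > 1 and depth_dispersion > 0",
         call. = FALSE)
  # feasibility: mean gene span must fit on the genome
  mean_span <- mean(cfg$exons_per_gene) * mean(cfg$exon_length) +
    (mean(cfg$exons_per_gene) - 1) * mean(cfg$intron_length)
  if (cfg$n_genes * mean_span >
      cfg$n_chromosomes * as.numeric(cfg$chromosome_length))
    stop("gene models do not fit on the genome: ",
         "n_genes x mean gene span exceeds total genome length", call. = FALSE)
  invisible(cfg)
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat("Synthetic gene-trap screen configuration\n")
  cat(sprintf("  genome:      %d x %s bp, %d genes (%d-%d exons each)\n",
              x$n_chromosomes, format(x$chromosome_length, big.mark = ","),
              x$n_genes, x$exons_per_gene[1], x$exons_per_gene[2]))
  cat(sprintf("  library:     %s insertions\n",
              format(x$n_insertions, big.mark = ",")))
  cat(sprintf("  selection:   p(survive) = %g resistant / %g background; %d resistance gene(s)\n",
              x$p_survive_resistant, x$p_survive_background,
              length(x$resistance_genes)))
  cat(sprintf("  sequencing:  %d bp reads, depth ~ 1 + NB(mu = %g, size = %g)\n",
              x$read_length, x$depth_mean - 1, x$depth_dispersion))
  cat(sprintf("  seed:        %d\n", x$seed))
  invisible(x)
}

# Independent, documented RNG streams per simulator stage so that each
# operation is reproducible on its own and insensitive to whether earlier
# stages ran in the same session. Offsets stay far below .Machine$integer.max.
.stream_offset <- c(genome = 0L, insertions = 1L, selection = 2L, reads = 3L)

with_stream <- function(seed, stage, expr) {
  off <- .stream_offset[[stage]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed %% 536870912L) * 4L + off)
  expr
}
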