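#' Run a complete synthetic screen end to end
#'
#' Convenience driver that chains the whole pipeline: genome and gene-model
#' generation, insertion library simulation, drug selection, read synthesis,
#' exact-match mapping, insertion-site calling (proximity + singleton
#' filters), inactivating-insertion classification, and per-gene Fisher
#' enrichment of the selected pool against the unselected library.
#'
#' The control counts are taken from the full pre-selection library (every
#' simulated insertion, as in a control library sequenced before selection);
#' the selected counts come from sites recovered by mapping the synthesized
#' reads of the surviving cells.
#'
#' @param config a \code{\link{screen_sim_config}}; its
#'   \code{resistance_genes} may name genes (by id) or give integer indices
#'   into the generated gene set.
#' @param min_length mapper minimum read length (default 20).
#' @return list: \code{config}, \code{genome}, \code{genes}, \code{library}
#'   (all insertion events), \code{survivors}, \code{truth}, \code{sites}
#'   (called sites of the selected pool), \code{enrichment} (a
#'   \code{screen_enrichment} object).
#' @examples
#' \donttest{
#' cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 2e5,
#'                          n_genes = 20, n_insertions = 4000,
#'                          resistance_genes = "gene005", seed = 7)
#' res <- run_screen(cfg)
#' summary(res$enrichment)
#' }
#' @export
run_screen <- function(config, min_length = 20L) {
  gen <- generate_genome(config)
  rg <- config$resistance_genes
  if (length(rg) && all(grepl("^[0-9]+$", rg)))
    config$resistance_genes <- unique(gen$genes$gene_id)[as.integer(rg)]
  events <- simulate_insertions(gen$genome, config)
  survivors <- apply_selection(events, gen$genes, config)
  if (!nrow(survivors))
    stop("no cells survived selection; raise the survival probabilities ",
         "or the library size", call. = FALSE)
  synth <- synthesize_reads(survivors, gen$genome, config)
  aligned <- map_reads(synth$reads, gen$genome, min_length = min_length,
                       vector_prefix = config$ltr_prefix)
  sites <- call_sites(aligned)
  selected_counts <- per_gene_counts(sites, gen$genes)
  control_counts <- per_gene_counts(events, gen$genes)
  enr <- screen_enrichment(selected_counts, control_counts)
  list(config = config, genome = gen$genome, genes = gen$genes,
       library = events, survivors = survivors, truth = synth$truth,
       sites = sites, enrichment = enr)
}
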