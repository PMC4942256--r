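test_that("the enrichment p-value is the hypergeometric upper tail", {
  expect_equal(fisher_enrichment(0, 10, 3, 100), 1)  # k = 0 covers everything
  # two-table enumeration by hand: margins (1,1), one success total
  expect_equal(fisher_enrichment(1, 1, 0, 1), 0.5)
  expect_equal(fisher_enrichment(5, 10, 1, 100),
               hyper_tail_oracle(5, 10, 1, 100), tolerance = 1e-12)
  # zero control cell: finite p without pseudocounts
  expect_lt(fisher_enrichment(4, 10, 0, 100), 1)
  expect_gt(fisher_enrichment(4, 10, 0, 100), 0)

  expect_error(fisher_enrichment(-1, 5, 0, 5), "non-negative")
  expect_error(fisher_enrichment(6, 5, 0, 5), "exceed")
})

test_that("enrichment p matches exact enumeration on all small tables", {
  for (n_sel in c(1, 3, 7, 12, 20)) {
    for (n_ctrl in c(1, 5, 11, 20)) {
      for (k_tot in 0:(n_sel + n_ctrl)) {
        ks <- max(0, k_tot - n_ctrl):min(n_sel, k_tot)
        for (k_sel in ks) {
          expect_equal(
            fisher_enrichment(k_sel, n_sel, k_tot - k_sel, n_ctrl),
            hyper_tail_oracle(k_sel, n_sel, k_tot - k_sel, n_ctrl),
            tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment p agrees with fisher.test and is monotone in k_sel", {
  set.seed(23)
  for (i in 1:25) {
    n_sel <- sample(1:60, 1); n_ctrl <- sample(1:60, 1)
    k_sel <- sample(0:n_sel, 1); k_ctrl <- sample(0:n_ctrl, 1)
    ft <- stats::fisher.test(
      matrix(c(k_sel, n_sel - k_sel, k_ctrl, n_ctrl - k_ctrl), 2,
             byrow = TRUE), alternative = "greater")
    expect_equal(fisher_enrichment(k_sel, n_sel, k_ctrl, n_ctrl),
                 ft$p.value, tolerance = 1e-9)
  }
  # at fixed margins p is non-increasing as the selected cell grows
  n_sel <- 15; n_ctrl <- 40; k_tot <- 12
  p <- vapply(max(0, k_tot - n_ctrl):min(n_sel, k_tot), function(x) {
    fisher_enrichment(x, n_sel, k_tot - x, n_ctrl)
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-14))
})

counts_frame <- function(gene_id, k, reads = k, chrom = "chr1",
                         start = seq_along(gene_id) * 1000L) {
  data.frame(gene_id = gene_id, chrom = chrom, start = start,
             n_inactivating_sites = as.integer(k),
             total_reads = as.integer(reads), stringsAsFactors = FALSE)
}

test_that("screen_enrichment builds the per-gene table with totals as margins", {
  sel <- counts_frame(c("g1", "g2", "g3"), c(8, 1, 0), reads = c(40, 5, 0))
  ctl <- counts_frame(c("g1", "g2", "g3"), c(2, 50, 30))
  enr <- screen_enrichment(sel, ctl)
  expect_s3_class(enr, "screen_enrichment")
  expect_equal(enr$n_selected_total, 9)
  expect_equal(enr$n_control_total, 82)
  tab <- as.data.frame(enr)
  expect_equal(tab$p_value[tab$gene_id == "g1"],
               fisher_enrichment(8, 9, 2, 82))
  expect_equal(tab$bubble_n, tab$k_selected)
  expect_equal(tab$chrom_order_index, 1:3)   # chromosomal order on x
  expect_equal(tab$bh_q, stats::p.adjust(tab$p_value, "BH"))

  bad <- counts_frame(c("g1", "g2", "g4"), c(1, 1, 1))
  expect_error(screen_enrichment(sel, bad), "g4")
})

test_that("a control-proportional selected pool shows no enrichment", {
  set.seed(29)
  k_ctrl <- rpois(150, 20) + 1L
  ctl <- counts_frame(sprintf("g%03d", 1:150), k_ctrl)
  sel <- ctl
  sel$n_inactivating_sites <- as.integer(round(k_ctrl / 4))
  enr <- screen_enrichment(sel, ctl)
  expect_gte(min(as.data.frame(enr)$p_value), 0.05)
})

test_that("planted resistance genes dominate a small end-to-end screen", {
  cfg <- screen_sim_config(n_chromosomes = 1, chromosome_length = 3e5,
                           n_genes = 25, n_insertions = 8000,
                           resistance_genes = c("5", "12", "20"),
                           seed = 37)
  res <- suppressWarnings(run_screen(cfg))
  tab <- as.data.frame(res$enrichment)
  top3 <- tab$gene_id[order(tab$p_value, tab$gene_id)][1:3]
  expect_setequal(top3, c("gene005", "gene012", "gene020"))
  # clear separation from the background even at this small scale
  expect_lt(max(tab$p_value[tab$gene_id %in% top3]), 1e-4)
  expect_gte(min(tab$p_value[!tab$gene_id %in% top3]), 0.05)
})

test_that("the display filter drops genes strictly below the read threshold", {
  sel <- counts_frame(c("g1", "g2", "g3", "g4"), c(3, 3, 3, 3),
                      reads = c(9, 10, 50, 49))
  ctl <- counts_frame(c("g1", "g2", "g3", "g4"), c(5, 5, 5, 5))
  enr <- screen_enrichment(sel, ctl)
  expect_setequal(display_filter(enr, 10)$table$gene_id, c("g2", "g3", "g4"))
  expect_setequal(display_filter(enr, 50)$table$gene_id, "g3")
  expect_equal(nrow(display_filter(enr, 0)$table), 4L)  # identity
})

test_that("published control-library totals are the validation reference", {
  models <- toy_models()
  sites <- rbind(site_row("chr1", 120, "+", 3),
                 site_row("chr1", 270, "-", 2),
                 site_row("chr2", 20, "+", 2))
  v <- validate_screen_counts(sites, models,
                              reference = c(unique_insertions = 3,
                                            inactivating_insertions = 1),
                              gene = "geneA", gene_reference = 1)
  expect_equal(v$observed, c(3, 1, 1))
  expect_true(all(v$match))
  # defaults carry the published screen's control-library totals
  d <- validate_screen_counts(sites, models)
  expect_equal(d$reference[1:2], c(142800, 38628))
})

test_that("print, summary and plot methods run on a fitted screen", {
  sel <- counts_frame(c("g1", "g2"), c(6, 1), reads = c(30, 12))
  ctl <- counts_frame(c("g1", "g2"), c(2, 40))
  enr <- screen_enrichment(sel, ctl)
  expect_output(print(enr), "top genes")
  s <- summary(enr)
  expect_output(print(s), "genes with p")
  expect_identical(s$table$gene_id[1], "g1")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(enr, min_total_reads = 0))
})
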