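# Shared fixtures built in code.

# A deterministic motif-free backbone: "ACG" repeated contains neither TTAA
# nor CATG, so restriction-site behaviour can be planted precisely.
motif_free <- function(n) substr(strrep("ACG", ceiling(n / 3)), 1, n)

# Tiny hand-laid annotation used across classification tests:
#  geneA chr1 + exons [100,200) and [300,400)  (intron [200,300))
#  geneB chr1 - exons [150,250)                (overlaps geneA)
#  geneC chr2 - exons [50,80) and [120,160)    (intron [80,120))
toy_models <- function() {
  data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneC", "geneC"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "+", "-", "-", "-"),
    start = c(100L, 300L, 150L, 50L, 120L),
    end = c(200L, 400L, 250L, 80L, 160L),
    stringsAsFactors = FALSE)
}

site_row <- function(chrom, pos, orientation, read_count = 1L) {
  data.frame(chrom = chrom, pos = as.integer(pos), orientation = orientation,
             read_count = as.integer(read_count), stringsAsFactors = FALSE)
}

sites_table <- function(pos, chrom = "chr1", orientation = "+",
                        read_count = 1L) {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             orientation = rep_len(orientation, length(pos)),
             read_count = rep_len(as.integer(read_count), length(pos)),
             stringsAsFactors = FALSE)
}

# Brute-force O(n^2) proximity filter: drop every site with another site on
# the same chromosome at |delta pos| of 1 or 2, regardless of orientation.
proximal_oracle <- function(sites) {
  drop <- vapply(seq_len(nrow(sites)), function(i) {
    d <- abs(sites$pos - sites$pos[i])
    any(sites$chrom == sites$chrom[i] & d >= 1L & d <= 2L)
  }, logical(1))
  out <- sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force exact search of a read over both strands of a genome given as
# a named character vector; returns a data.frame of all placements with the
# package's coordinate convention.
bruteforce_map <- function(seq, genome_chr) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  hits <- list()
  for (cn in names(genome_chr)) {
    g <- genome_chr[[cn]]
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") seq else rc
      m <- gregexpr(pat, g, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      # gregexpr misses overlapping matches; rescan from each hit + 1
      starts <- integer(0)
      from <- 1L
      repeat {
        k <- regexpr(pat, substr(g, from, nchar(g)), fixed = TRUE)
        if (k == -1) break
        starts <- c(starts, from + k - 1L)
        from <- from + k
      }
      for (s in starts) {
        pos0 <- if (ori == "+") s - 1L else s - 1L + nchar(seq) - 1L
        hits[[length(hits) + 1L]] <-
          data.frame(chrom = cn, pos = pos0, orientation = ori,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(0), pos = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# Exact hypergeometric upper-tail oracle. All binomial coefficients involved
# are exact in double precision for margins <= 20 (max C(40,20) < 2^53), so
# the sum is an exact rational computed in floating point without rounding
# of the inputs.
hyper_tail_oracle <- function(k_sel, n_sel, k_ctrl, n_ctrl) {
  m <- k_sel + k_ctrl
  x <- seq(k_sel, min(n_sel, m))
  if (k_sel > min(n_sel, m)) return(1)  # unreachable for valid tables
  num <- sum(choose(n_sel, x) * choose(n_ctrl, m - x))
  num / choose(n_sel + n_ctrl, m)
}
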