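#' Collapse aligned reads into unique insertion sites
#'
#' One site per distinct (chromosome, position, orientation), carrying the
#' number of contributing reads, sorted by chromosome then position.
#'
#' @param aligned data.frame (read_id, chrom, pos, orientation) from
#'   \code{\link{map_reads}} or \code{\link{import_external_alignments}}.
#' @return data.frame: chrom, pos, orientation, read_count.
#' @export
collapse_sites <- function(aligned) {
  if (!nrow(aligned))
    return(data.frame(chrom = character(0), pos = integer(0),
                      orientation = character(0), read_count = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(aligned$chrom, aligned$pos, aligned$orientation, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1L),
                    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
                    orientation = vapply(parts, `[`, character(1), 3L),
                    read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard sites separated by only 1 or 2 bp
#'
#' Alignment jitter of a single junction can report the same insertion at
#' positions 1-2 bp apart, so any site with another site on the same
#' chromosome at distance 1 or 2 bp (irrespective of orientation) is removed.
#' By default removal is symmetric: every member of such a proximal cluster
#' goes. With \code{keep_max_reads = TRUE} the highest-read-count member of
#' each connected cluster is retained instead (ties broken by position), for
#' sensitivity analysis.
#'
#' @param sites site table from \code{\link{collapse_sites}}.
#' @param keep_max_reads retain the best-supported member of each cluster.
#' @return filtered site table.
#' @export
filter_proximal <- function(sites, keep_max_reads = FALSE) {
  if (nrow(sites) < 2L) return(sites)
  keep <- rep(TRUE, nrow(sites))
  for (cn in unique(sites$chrom)) {
    rows <- which(sites$chrom == cn)
    up <- sort(unique(sites$pos[rows]))
    if (length(up) < 2L) next
    # proximity is between distinct positions; distance 0 (opposite
    # orientations at one position) never triggers the filter
    d <- diff(up)
    close_pair <- d >= 1L & d <= 2L
    prox_pos <- c(FALSE, close_pair) | c(close_pair, FALSE)
    if (!any(prox_pos)) next
    if (!keep_max_reads) {
      keep[rows[sites$pos[rows] %in% up[prox_pos]]] <- FALSE
    } else {
      # connected clusters of positions under the <= 2 bp adjacency
      cluster <- cumsum(c(TRUE, !close_pair))
      for (cl in unique(cluster[prox_pos])) {
        members <- rows[sites$pos[rows] %in% up[cluster == cl]]
        best <- members[which.max(sites$read_count[members])]
        keep[setdiff(members, best)] <- FALSE
      }
    }
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard sites supported by a single read
#'
#' Sites represented by only one sequencing read are removed.
#'
#' @param sites site table.
#' @param min_reads minimum read support to retain (default 2, i.e. drop
#'   singletons).
#' @return filtered site table.
#' @export
filter_singletons <- function(sites, min_reads = 2L) {
  out <- sites[sites$read_count >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call insertion sites from aligned reads
#'
#' Convenience wrapper: collapse, then the proximity filter, then the
#' single-read filter, in that order.
#'
#' @inheritParams collapse_sites
#' @inheritParams filter_proximal
#' @return filtered site table.
#' @export
call_sites <- function(aligned, keep_max_reads = FALSE) {
  filter_singletons(filter_proximal(collapse_sites(aligned),
                                    keep_max_reads = keep_max_reads))
}

#' Diagnose filter-order sensitivity
#'
#' Applies the proximity and singleton filters in both orders and reports
#' the sites on which the results differ. The singleton filter can remove a
#' member of a proximal pair, letting its partner survive when the proximity
#' filter runs second; this diagnostic makes that difference visible.
#'
#' @param sites collapsed site table.
#' @return list with \code{prox_first}, \code{singleton_first}, and
#'   \code{difference} (sites present in exactly one result).
#' @export
filter_order_diagnostic <- function(sites) {
  a <- filter_singletons(filter_proximal(sites))
  b <- filter_proximal(filter_singletons(sites))
  key <- function(x) paste(x$chrom, x$pos, x$orientation)
  only_a <- a[!key(a) %in% key(b), , drop = FALSE]
  only_b <- b[!key(b) %in% key(a), , drop = FALSE]
  diff <- rbind(only_a, only_b)
  rownames(diff) <- NULL
  list(prox_first = a, singleton_first = b, difference = diff)
}

#' Read or write a site table as TSV
#'
#' Columns: chrom, pos (0-based), orientation, read_count.
#' @param sites site table.
#' @param path file path.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character",
                                   orientation = "character"),
                    stringsAsFactors = FALSE)
}
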