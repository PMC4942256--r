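#' Trim reads after the first restriction site
#'
#' Inverse-PCR fragments terminate at an MseI (TTAA) or NlaIII (CATG) site, so
#' any bases past the first such site are vector-derived and would defeat
#' exact-match alignment of fragments shorter than the read length. If either
#' motif occurs in the read the prefix ending at the last base of the leftmost
#' occurrence is returned (the restriction site itself is retained); otherwise
#' the read is unchanged. The operation is idempotent and always returns a
#' prefix of its input.
#'
#' @param reads character vector of read sequences, or a data.frame with a
#'   \code{sequence} column.
#' @return same shape as the input, trimmed.
#' @examples
#' trim_at_restriction_site("ACGTTTAACCGGTT")  # "ACGTTTAA"
#' @export
trim_at_restriction_site <- function(reads) {
  if (is.data.frame(reads)) {
    reads$sequence <- trim_at_restriction_site(reads$sequence)
    return(reads)
  }
  hit <- regexpr("TTAA|CATG", reads)
  found <- hit > 0L
  reads[found] <- substr(reads[found], 1L, hit[found] + 3L)
  reads
}

#' Remove a literal vector-sequence prefix from reads
#'
#' When library preparation leaves a fixed stretch of vector (LTR) sequence at
#' the 5' end of every read, it is removed by literal prefix match before
#' restriction-site trimming. Reads not starting with the prefix are returned
#' unchanged.
#'
#' @param reads character vector or data.frame with a \code{sequence} column.
#' @param prefix the vector sequence to strip; \code{""} is a no-op.
#' @export
strip_vector_prefix <- function(reads, prefix = "") {
  if (!nzchar(prefix)) return(reads)
  if (is.data.frame(reads)) {
    reads$sequence <- strip_vector_prefix(reads$sequence, prefix)
    return(reads)
  }
  has <- startsWith(reads, prefix)
  reads[has] <- substring(reads[has], nchar(prefix) + 1L)
  reads
}

#' Map reads to a genome by unique exact match
#'
#' A read is retained if and only if it is at least \code{min_length} bp long
#' and matches the genome exactly (no mismatches) at exactly one place over
#' both strands. The reported position is the 0-based forward-strand
#' coordinate of the read's first base: for a forward match the match start;
#' for a reverse-strand match the forward-strand coordinate of the junction
#' base, i.e. the last base of the reverse-complement match. This keeps the
#' insertion-position convention strand-symmetric with the simulator.
#'
#' @param reads data.frame (read_id, sequence) or character vector (ids are
#'   generated).
#' @param genome named \code{DNAStringSet}, or FASTA path.
#' @param min_length minimum retained read length after trimming (default 20).
#' @param vector_prefix optional literal 5' vector sequence removed before
#'   trimming.
#' @return data.frame: \code{read_id}, \code{chrom}, \code{pos} (0-based),
#'   \code{orientation}.
#' @export
map_reads <- function(reads, genome, min_length = 20L, vector_prefix = "") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%07d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  reads <- strip_vector_prefix(reads, vector_prefix)
  reads <- trim_at_restriction_site(reads)
  reads <- reads[nchar(reads$sequence) >= min_length, , drop = FALSE]
  if (!nrow(reads))
    return(data.frame(read_id = character(0), chrom = character(0),
                      pos = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))

  uniq <- unique(reads$sequence)
  place <- lapply(uniq, function(s) locate_unique(s, genome))
  names(place) <- uniq
  hits <- place[reads$sequence]
  ok <- !vapply(hits, is.null, logical(1))
  out <- data.frame(
    read_id = reads$read_id[ok],
    chrom = vapply(hits[ok], `[[`, character(1), "chrom"),
    pos = vapply(hits[ok], `[[`, integer(1), "pos"),
    orientation = vapply(hits[ok], `[[`, character(1), "orientation"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Exact search of one sequence over both strands of every chromosome.
# Returns NULL unless there is exactly one match genome-wide.
locate_unique <- function(seq, genome) {
  fwd <- Biostrings::vmatchPattern(seq, genome)
  rev <- Biostrings::vmatchPattern(revcomp(seq), genome)
  nf <- vapply(fwd, length, integer(1))
  nr <- vapply(rev, length, integer(1))
  if (sum(nf) + sum(nr) != 1L) return(NULL)
  if (sum(nf) == 1L) {
    ci <- which(nf == 1L)
    m <- fwd[[ci]]
    list(chrom = names(genome)[ci],
         pos = as.integer(BiocGenerics::start(m) - 1L), orientation = "+")
  } else {
    ci <- which(nr == 1L)
    m <- rev[[ci]]
    list(chrom = names(genome)[ci],
         pos = as.integer(BiocGenerics::end(m) - 1L), orientation = "-")
  }
}

#' Read single-end reads from FASTQ or FASTA
#'
#' @param path FASTQ (or FASTA) file.
#' @return data.frame (read_id, sequence).
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(read_id = sub(" .*", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Import externally produced alignments
#'
#' Escape hatch for data aligned at genome scale with an external aligner.
#' Accepts coordinate-sorted SAM or BAM; records with any mapping ambiguity
#' (unmapped, secondary, supplementary, or MAPQ 0) are dropped, and 1-based
#' SAM coordinates are converted to the internal 0-based convention. For
#' reverse-strand records the reported position is the leftmost aligned base,
#' per SAM convention.
#'
#' @param path SAM or BAM file, coordinate-sorted, with a header.
#' @return data.frame: read_id, chrom, pos (0-based), orientation.
#' @export
import_external_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  hd <- grep("^@HD", names(hdr$text), value = FALSE)
  so <- unlist(hdr$text[names(hdr$text) == "@HD"])
  if (!length(so) || !any(grepl("^SO:coordinate$", so)))
    stop("alignments must be coordinate-sorted (header SO:coordinate)",
         call. = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "strand", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq > 0L
  data.frame(read_id = rec$qname[keep],
             chrom = as.character(rec$rname[keep]),
             pos = rec$pos[keep] - 1L,
             orientation = ifelse(as.character(rec$strand[keep]) == "-",
                                  "-", "+"),
             stringsAsFactors = FALSE)
}
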