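#' Read a (possibly soft-masked) genome FASTA
#'
#' Reads a multi-record FASTA preserving case (lowercase soft-masking) and
#' `N` runs. Sequences are returned as plain character strings so that the
#' masking and gap structure the partitioning rules depend on is untouched.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param allowed_ids Optional character vector of record names to keep, in
#'   file order. `NULL` keeps everything.
#' @param lenient If `FALSE` (default) any character outside
#'   `A,C,G,T,N,a,c,g,t,n` is an error; if `TRUE`, IUPAC ambiguity codes are
#'   mapped to `N` (case preserved) and anything else still errors.
#' @return A data.frame with columns `id`, `seq`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allowed_ids = NULL, lenient = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)  # BStringSet: bytes kept verbatim
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (!is.null(allowed_ids)) {
    keep <- ids %in% allowed_ids
    if (!any(keep)) stop("no FASTA records match the requested ids")
    ids <- ids[keep]
    seqs <- seqs[keep]
  }
  if (lenient) {
    iupac <- "RYSWKMBDHVryswkmbdhv"
    seqs <- chartr(iupac, paste(rep(c("N", "n"), each = 10), collapse = ""),
                   seqs)
  }
  bad <- regexpr("[^ACGTNacgtn]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' at position %d of record '%s'%s",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i],
                 if (lenient) "" else " (use lenient = TRUE for IUPAC codes)"))
  }
  data.frame(id = unname(ids), seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Default primary-chromosome name filter
#'
#' The 24 primary human chromosome names (22 autosomes plus X and Y) in UCSC
#' style; the analysis of a human assembly is restricted to these.
#'
#' @return Character vector `chr1` ... `chr22`, `chrX`, `chrY`.
#' @export
primary_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

run_regex <- function(seqs, pattern) {
  m <- gregexpr(pattern, seqs)
  lapply(seq_along(seqs), function(i) {
    st <- m[[i]]
    if (length(st) == 1L && st[1] == -1L) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    len <- attr(st, "match.length")
    data.frame(start = as.integer(st) - 1L, end = as.integer(st) - 1L + len)
  })
}

build_partition_set <- function(records, pattern, mode) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  runs <- run_regex(records$seq, pattern)
  parts <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    r <- runs[[i]]
    if (nrow(r) == 0) return(NULL)
    data.frame(chrom = records$id[i], start = r$start, end = r$end,
               seq = toupper(substring(records$seq[i], r$start + 1L, r$end)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(parts)) {
    parts <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), seq = character(0))
  }
  parts$length <- parts$end - parts$start
  n_unfinished <- sum(nchar(gsub("[^Nn]", "", records$seq)))
  n_masked <- sum(nchar(gsub("[^acgt]", "", records$seq)))
  structure(list(
    partitions = parts[, c("chrom", "start", "end", "length", "seq")],
    mode = mode,
    finished_bases = sum(parts$length),
    unfinished_bases = n_unfinished,
    masked_bases = if (mode == "softmask-split") n_masked else 0L,
    total_bases = sum(records$length),
    chrom_lengths = stats::setNames(records$length, records$id)
  ), class = "partition_set")
}

#' Partition a genome on assembly gaps (N runs)
#'
#' Runs of `N`/`n` mark unfinished sequence and cut each chromosome into
#' finished blocks; k-mers are never taken across a block boundary.
#' Lowercase (soft-masked) bases inside blocks are uppercased and kept: this
#' is the all-inclusive analysis mode.
#'
#' @param records Data.frame from [read_fasta()].
#' @return A `partition_set`: `$partitions` (chrom, start, end, length, seq;
#'   0-based half-open coordinates), `$finished_bases`, `$unfinished_bases`
#'   (N count), `$total_bases`, `$chrom_lengths`, `$mode = "gap-split"`.
#' @examples
#' rec <- data.frame(id = "c", seq = "ACGNNGT", length = 7)
#' partition_on_gaps(rec)$partitions
#' @export
partition_on_gaps <- function(records) {
  build_partition_set(records, "[ACGTacgt]+", "gap-split")
}

#' Partition a genome on soft-masked (lowercase) runs
#'
#' Both lowercase runs (RepeatMasker-style soft-masking) and `N` runs break
#' blocks, leaving only uppercase A/C/G/T sequence: the repeat-filtered
#' analysis mode. Masked bases are tallied in `$masked_bases`.
#'
#' @inheritParams partition_on_gaps
#' @return A `partition_set` with `mode = "softmask-split"`.
#' @export
partition_on_softmask <- function(records) {
  build_partition_set(records, "[ACGT]+", "softmask-split")
}

#' Histogram of partition lengths
#'
#' @param pset A `partition_set`.
#' @param breaks Passed to [graphics::hist()]-style binning via [cut()];
#'   default powers of ten covering the observed range.
#' @param threshold Length (bp) below which the reported fraction is
#'   computed (repeat-filtered blocks are mostly sub-kb, which limits the
#'   usable k on that mode).
#' @return List with `histogram` (data.frame bin, count) and
#'   `fraction_below` (fraction of partitions shorter than `threshold`).
#' @export
partition_length_histogram <- function(pset, breaks = NULL, threshold = 1000) {
  stopifnot(inherits(pset, "partition_set"))
  len <- pset$partitions$length
  if (length(len) == 0) stop("partition set is empty")
  if (is.null(breaks)) {
    breaks <- 10^(0:ceiling(log10(max(len) + 1)))
  }
  cuts <- cut(len, breaks = breaks, right = FALSE, include.lowest = TRUE)
  tab <- table(cuts)
  list(histogram = data.frame(bin = names(tab), count = as.integer(tab),
                              stringsAsFactors = FALSE),
       fraction_below = mean(len < threshold))
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf(
    "partition_set (%s): %d partitions over %d sequence(s)\n",
    x$mode, nrow(x$partitions), length(x$chrom_lengths)))
  cat(sprintf("  finished: %s bp | unfinished (N): %s bp%s | total: %s bp\n",
              format(x$finished_bases, big.mark = ","),
              format(x$unfinished_bases, big.mark = ","),
              if (x$mode == "softmask-split")
                sprintf(" | masked: %s bp", format(x$masked_bases, big.mark = ","))
              else "",
              format(x$total_bases, big.mark = ",")))
  invisible(x)
}

#' Write a partition table as TSV
#'
#' Columns chrom, start, end, length, mode; BED-compatible 0-based
#' half-open coordinates.
#'
#' @param pset A `partition_set`.
#' @param path Output path.
#' @export
write_partitions <- function(pset, path) {
  stopifnot(inherits(pset, "partition_set"))
  df <- pset$partitions[, c("chrom", "start", "end", "length")]
  df$mode <- pset$mode
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a partition set
#'
#' @param pset A `partition_set`.
#' @return List (JSON-ready) of base totals and partition counts.
#' @export
partition_summary <- function(pset) {
  stopifnot(inherits(pset, "partition_set"))
  list(mode = pset$mode,
       n_partitions = nrow(pset$partitions),
       finished_bases = pset$finished_bases,
       unfinished_bases = pset$unfinished_bases,
       masked_bases = pset$masked_bases,
       total_bases = pset$total_bases)
}

#' Build a partition set directly from sequences
#'
#' Convenience for analyses and tests that start from in-memory sequence
#' strings rather than a FASTA file.
#'
#' @param seqs Character vector of sequences (named or not).
#' @param mode `"gap-split"` or `"softmask-split"`.
#' @return A `partition_set`.
#' @export
partition_strings <- function(seqs, mode = c("gap-split", "softmask-split")) {
  mode <- match.arg(mode)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rec <- data.frame(id = ids, seq = unname(seqs), length = nchar(seqs),
                    stringsAsFactors = FALSE)
  if (mode == "gap-split") partition_on_gaps(rec) else partition_on_softmask(rec)
}
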