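#' Reverse complement
#'
#' @param s Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGC")  # "GCTT"
#' @export
reverse_complement <- function(s) cpp_revcomp(as.character(s))

#' Canonical k-mer
#'
#' The representative of a k-mer type: the lexicographically smaller
#' (A < C < G < T) of a string and its reverse complement. A k-mer and its
#' reverse complement are the same type, e.g. `AAGC`/`GCTT`.
#'
#' @param s Character vector of ACGT strings.
#' @return Character vector of canonical forms.
#' @examples
#' canonical_kmer(c("AAGC", "TTTT", "GAT"))
#' @export
canonical_kmer <- function(s) cpp_canonical(as.character(s))

# exact decimal-string arithmetic (no bignum package in the stack):
# digits little-endian base 10
dec_double <- function(d) {
  d <- d * 2L
  carry <- 0L
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% 10L
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    d <- c(d, carry %% 10L)
    carry <- carry %/% 10L
  }
  d
}

dec_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a)))
  b <- c(b, integer(n - length(b)))
  s <- a + b
  carry <- 0L
  for (i in seq_len(n)) {
    v <- s[i] + carry
    s[i] <- v %% 10L
    carry <- v %/% 10L
  }
  if (carry > 0L) s <- c(s, carry)
  s
}

dec_pow2 <- function(n) {
  d <- 1L
  for (i in seq_len(n)) d <- dec_double(d)
  d
}

dec_string <- function(d) paste(rev(d), collapse = "")

#' Number of distinct canonical k-mer types
#'
#' Counting a string and its reverse complement as one type, the number of
#' k-mer types is `4^k / 2` for odd k and `(4^k + 2^k) / 2` for even k (the
#' `2^k` term counts the reverse-complement palindromes, which pair with
#' themselves).
#'
#' @param k k-mer length (bp), `k >= 1`.
#' @param exact If `TRUE`, return the exact integer as a decimal character
#'   string (arbitrary precision). The default numeric return is exact only
#'   up to `k = 26` (beyond that `2^(2k-1)` exceeds double precision).
#' @return Numeric count, or a decimal string when `exact = TRUE`.
#' @examples
#' kmer_type_count(2)            # 10
#' kmer_type_count(17)           # 8589934592 = 4^17 / 2
#' kmer_type_count(40, exact = TRUE)
#' @export
kmer_type_count <- function(k, exact = FALSE) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != floor(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  if (exact) {
    d <- dec_pow2(2L * k - 1L)                     # 4^k / 2
    if (k %% 2L == 0L) d <- dec_add(d, dec_pow2(k - 1L))  # + 2^k / 2
    return(dec_string(d))
  }
  n <- 2^(2 * k - 1)
  if (k %% 2 == 0) n <- n + 2^(k - 1)
  n
}

#' Smallest k whose type space covers a genome
#'
#' The smallest k-mer length for which the number of distinct canonical
#' types is at least the genome size; below this, repeats are unavoidable
#' in any sequence of that size. For a 3 Gb genome this gives k = 17.
#'
#' @param genome_size Genome size in bases (`>= 1`).
#' @return Integer k.
#' @examples
#' min_k_unique(3e9)  # 17
#' @export
min_k_unique <- function(genome_size) {
  if (length(genome_size) != 1 || is.na(genome_size) || genome_size < 1)
    stop("genome_size must be a single number >= 1")
  k <- 1L
  while (kmer_type_count(k) < genome_size) k <- k + 1L
  k
}

as_partitions <- function(x) {
  if (inherits(x, "partition_set")) return(x$partitions$seq)
  if (is.character(x)) return(x)
  stop("expected a partition_set or a character vector of sequences")
}

#' Count canonical k-mers over a partition set
#'
#' One token per window position per partition; windows never span a
#' partition boundary. Two strategies give identical tables: an in-memory
#' hash (fast, RAM proportional to distinct types) and a two-pass
#' disk-bucketed counter in the style of DSK, which spills canonical tokens
#' to `n_buckets` temporary files hashed by k-mer and counts each bucket
#' independently, bounding RAM at roughly `1/n_buckets` of the type space.
#'
#' @param x A `partition_set` or a character vector of ACGT sequences.
#' @param k k-mer length (bp).
#' @param strategy `"auto"` (default; disk when the estimated table exceeds
#'   `max_ram`), `"memory"`, or `"disk"`.
#' @param n_buckets Number of disk buckets (disk strategy); default chosen
#'   from the RAM estimate.
#' @param max_ram Approximate RAM budget in bytes for the auto strategy.
#' @param workdir Directory for spill files (disk strategy).
#' @return A `kmer_count_table`: list with `k`, `kmer` (canonical strings,
#'   sorted), `count` (frequencies f), `total_tokens`, `n_types`.
#' @examples
#' count_kmers("ACGT", k = 2)   # AC:2 (GT collapses onto AC), CG:1
#' @export
count_kmers <- function(x, k, strategy = c("auto", "memory", "disk"),
                        n_buckets = NULL, max_ram = 2e9, workdir = tempdir()) {
  strategy <- match.arg(strategy)
  parts <- as_partitions(x)
  if (length(k) != 1 || is.na(k) || k < 1 || k != floor(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  n_windows <- sum(pmax(0, nchar(parts) - k + 1))
  # ~ (k + 64) bytes per distinct type is a coarse hash-table estimate
  est_bytes <- n_windows * (k + 64)
  if (strategy == "auto")
    strategy <- if (est_bytes > max_ram) "disk" else "memory"
  if (n_windows == 0) {
    warning("k = ", k, " exceeds every partition length; empty table")
    res <- list(kmer = character(0), count = numeric(0), total_tokens = 0)
  } else if (strategy == "memory") {
    res <- cpp_count_kmers_mem(parts, k)
  } else {
    if (is.null(n_buckets))
      n_buckets <- max(1L, as.integer(ceiling(est_bytes / max_ram)))
    spill <- file.path(workdir, paste0("kmermap_", Sys.getpid(), "_",
                                       as.integer(stats::runif(1, 0, 1e8))))
    dir.create(spill, recursive = TRUE, showWarnings = FALSE)
    on.exit(unlink(spill, recursive = TRUE), add = TRUE)
    res <- cpp_count_kmers_disk(parts, k, as.integer(n_buckets), spill)
  }
  structure(list(k = k, kmer = res$kmer, count = res$count,
                 total_tokens = res$total_tokens,
                 n_types = length(res$kmer)),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: k = %d, %s types, %s tokens, max f = %s\n",
              x$k, format(x$n_types, big.mark = ","),
              format(x$total_tokens, big.mark = ","),
              if (x$n_types) format(max(x$count), big.mark = ",") else "NA"))
  invisible(x)
}

check_table <- function(table) {
  if (!inherits(table, "kmer_count_table")) stop("expected a kmer_count_table")
  if (table$n_types == 0) stop("empty k-mer count table")
  invisible(table)
}

#' Non-singleton proportion (p_ns)
#'
#' Singletons are types with frequency f = 1; every other type is a
#' non-singleton. At token level (the default, the mappability measure)
#' p_ns is the fraction of window positions whose type occurs more than
#' once, i.e. the fraction of length-k reads drawn from the genome that
#' cannot be uniquely placed. At type level it is the fraction of distinct
#' types with f > 1.
#'
#' @param table A `kmer_count_table`.
#' @param level `"token"` (default) or `"type"`.
#' @return Fraction in \[0, 1\].
#' @examples
#' non_singleton_proportion(count_kmers("ACGT", 2))          # 2/3
#' non_singleton_proportion(count_kmers("ACGT", 2), "type")  # 1/2
#' @export
non_singleton_proportion <- function(table, level = c("token", "type")) {
  level <- match.arg(level)
  check_table(table)
  ns <- table$count > 1
  if (level == "token") sum(table$count[ns]) / table$total_tokens
  else sum(ns) / table$n_types
}

chrom_windows <- function(pset, k) {
  sum(pmax(0, pset$chrom_lengths - k + 1))
}

#' Non-singleton proportion with unfinished sequence as non-singleton
#'
#' The pessimistic variant: every window position per chromosome that is
#' not a finished token (it overlaps an N run or a partition boundary) is
#' counted as non-singleton, reflecting that reads from unfinished regions
#' can never be uniquely mapped. The denominator is the per-chromosome
#' window count `sum(length - k + 1)`.
#'
#' @param table `kmer_count_table` counted from `pset` at the same k.
#' @param pset The gap-split `partition_set` the table came from.
#' @param k k-mer length used.
#' @return Fraction in \[0, 1\].
#' @export
non_singleton_with_gaps <- function(table, pset, k) {
  check_table(table)
  if (!inherits(pset, "partition_set") || pset$mode != "gap-split")
    stop("pset must be a gap-split partition_set")
  if (k != table$k) stop("k does not match the count table")
  denom <- chrom_windows(pset, k)
  if (denom <= 0) stop("k exceeds every chromosome length")
  ns_tokens <- sum(table$count[table$count > 1])
  (ns_tokens + (denom - table$total_tokens)) / denom
}

#' Maximum k-mer frequency
#'
#' The highest copy number among all types at this k; ties are broken by
#' the lexicographically smallest canonical k-mer for determinism.
#'
#' @param table A `kmer_count_table`.
#' @return List with `f` (max frequency) and `kmer` (exemplar).
#' @export
max_frequency <- function(table) {
  check_table(table)
  f <- max(table$count)
  # table is sorted by canonical k-mer, so the first hit is the smallest
  list(f = f, kmer = table$kmer[which.max(table$count == f)])
}

#' Mappability curve: p_ns and max f across a k grid
#'
#' One counting pass per k. The default grid spans the read lengths of
#' interest, 20 bp to 1000 bp.
#'
#' @param pset A `partition_set`.
#' @param k_grid Ascending vector of k values.
#' @param with_gaps Also compute the unfinished-as-non-singleton variant
#'   (gap-split mode only).
#' @param ... Passed to [count_kmers()] (strategy, workdir, ...).
#' @return Data.frame with one row per k: `k`, `p_ns` (token level),
#'   `p_ns_type`, `p_ns_with_gaps` (NA unless requested), `max_f`,
#'   `total_tokens`, `n_types`. k values whose windows are empty yield NA
#'   rows with a warning.
#' @export
mappability_curve <- function(pset, k_grid = default_k_grid(),
                              with_gaps = inherits(pset, "partition_set") &&
                                pset$mode == "gap-split", ...) {
  if (length(k_grid) == 0 || is.unsorted(k_grid, strictly = TRUE))
    stop("k_grid must be non-empty and strictly ascending")
  rows <- lapply(k_grid, function(k) {
    tab <- withCallingHandlers(
      count_kmers(pset, k, ...),
      warning = function(w) invokeRestart("muffleWarning"))
    if (tab$n_types == 0) {
      warning("no tokens at k = ", k, "; reported as NA")
      return(data.frame(k = k, p_ns = NA_real_, p_ns_type = NA_real_,
                        p_ns_with_gaps = NA_real_, max_f = NA_real_,
                        total_tokens = 0, n_types = 0))
    }
    data.frame(
      k = k,
      p_ns = non_singleton_proportion(tab, "token"),
      p_ns_type = non_singleton_proportion(tab, "type"),
      p_ns_with_gaps = if (with_gaps) non_singleton_with_gaps(tab, pset, k)
                       else NA_real_,
      max_f = max_frequency(tab)$f,
      total_tokens = tab$total_tokens,
      n_types = tab$n_types)
  })
  do.call(rbind, rows)
}

#' Default k grid for mappability curves
#'
#' @return `c(20, 30, 40, 50, 80, 100, 150, 200, 300, 400, 500, 700, 1000)`.
#' @export
default_k_grid <- function() {
  c(20, 30, 40, 50, 80, 100, 150, 200, 300, 400, 500, 700, 1000)
}

#' Write a count table as sorted TSV (+ JSON sidecar)
#'
#' @param table A `kmer_count_table`.
#' @param path TSV output path; a `.json` sidecar with k and totals is
#'   written next to it.
#' @export
write_count_table <- function(table, path) {
  check_table(table)
  utils::write.table(data.frame(kmer = table$kmer, f = table$count),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(k = table$k, total_tokens = table$total_tokens,
                            n_types = table$n_types),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
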