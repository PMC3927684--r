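#' Select high-frequency k-mer types
#'
#' @param table A `kmer_count_table`.
#' @param f_min Inclusive frequency threshold, `>= 2` (singletons are never
#'   high-frequency).
#' @return A `high_freq_set`: list with `k`, `kmer`, `f` (both restricted
#'   to types with f >= f_min) and `f_min`.
#' @export
select_high_frequency <- function(table, f_min) {
  check_table(table)
  if (length(f_min) != 1 || is.na(f_min) || f_min < 2)
    stop("f_min must be a single integer >= 2")
  keep <- table$count >= f_min
  structure(list(k = table$k, kmer = table$kmer[keep], f = table$count[keep],
                 f_min = f_min),
            class = "high_freq_set")
}

#' Locate every occurrence of high-frequency k-mers
#'
#' Exact canonical rescan of the partitioned genome (the k-mers came from
#' the same assembly with zero mismatches, so exact matching finds every
#' site an aligner would). Each window whose canonical form is in the set
#' is reported once, at its forward-strand position regardless of which
#' strand matched.
#'
#' @param pset A `partition_set`.
#' @param hfs A `high_freq_set`.
#' @return Data.frame of occurrences: `chrom`, `pos` (0-based window
#'   start, genome coordinates), `kmer` (canonical), sorted by position.
#' @export
locate_occurrences <- function(pset, hfs) {
  stopifnot(inherits(pset, "partition_set"), inherits(hfs, "high_freq_set"))
  p <- pset$partitions
  res <- cpp_locate(p$seq, p$chrom, as.numeric(p$start), hfs$k, hfs$kmer)
  occ <- data.frame(chrom = res$chrom, pos = res$pos, kmer = res$kmer,
                    stringsAsFactors = FALSE)
  occ <- occ[order(occ$chrom, occ$pos, method = "radix"), , drop = FALSE]
  rownames(occ) <- NULL
  structure(occ, k = hfs$k, class = c("occurrences", "data.frame"))
}

#' Merge high-frequency k-mer windows into regions
#'
#' Overlapping k-mers cluster into few regions: windows `[pos, pos+k)` on
#' one chromosome are merged when they overlap or their gap is at most
#' `max_gap` (default 0: overlap/abutment only). Per region the number of
#' distinct high-frequency types, the occurrence count, the maximum f
#' inside, and the end-to-start distance to the previous region on the
#' chromosome are reported.
#'
#' @param occs Occurrence data.frame from [locate_occurrences()].
#' @param k k-mer length (bp); defaults to the `k` attribute of `occs`.
#' @param max_gap Merge windows separated by at most this many bases.
#' @param freqs Optional named vector (canonical k-mer -> f) used for
#'   `max_f_inside`; taken from the occurrence multiplicities when absent.
#' @return Data.frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open), `n_kmer_types`, `n_occurrences`, `max_f_inside`,
#'   `dist_left` (NA for the first region on a chromosome).
#' @export
merge_windows <- function(occs, k = attr(occs, "k"), max_gap = 0,
                          freqs = NULL) {
  stopifnot(is.data.frame(occs), all(c("chrom", "pos", "kmer") %in% names(occs)))
  if (is.null(k)) stop("k must be supplied")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_kmer_types = integer(0),
                      n_occurrences = integer(0), max_f_inside = numeric(0),
                      dist_left = numeric(0))
  if (nrow(occs) == 0) return(empty)
  if (is.null(freqs)) freqs <- table(occs$kmer)
  gr <- GenomicRanges::GRanges(occs$chrom,
                               IRanges::IRanges(start = occs$pos + 1,
                                                width = k))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  by_region <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  by_region <- by_region[order(as.integer(names(by_region)))]
  n_types <- vapply(by_region, function(i) length(unique(occs$kmer[i])), 0L)
  n_occ <- vapply(by_region, length, 0L)
  max_f <- vapply(by_region, function(i)
    max(as.numeric(freqs[unique(occs$kmer[i])])), 0)
  reg <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = as.numeric(GenomicRanges::end(merged)),
    n_kmer_types = n_types, n_occurrences = n_occ, max_f_inside = max_f,
    stringsAsFactors = FALSE)
  reg <- reg[order(reg$chrom, reg$start, method = "radix"), , drop = FALSE]
  reg$dist_left <- ave(seq_len(nrow(reg)), reg$chrom, FUN = function(i) {
    c(NA, reg$start[i][-1] - reg$end[i][-length(i)])
  })
  rownames(reg) <- NULL
  structure(reg, k = k, class = c("regions", "data.frame"))
}

as_granges_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("chrom", "start", "end") %in% names(track)))
  if (is.null(track$label)) track$label <- "."
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1,
                                          end = track$end),
                         label = track$label)
}

#' Annotate regions against interval tracks
#'
#' Any positive-length intersection with a track interval is a hit;
#' touching half-open intervals are not. Reports, per region and track,
#' the overlapping labels and total overlap bp.
#'
#' @param regions Region data.frame from [merge_windows()].
#' @param tracks Named list of BED-like data.frames (`chrom`, `start`,
#'   `end`, `label`; 0-based half-open).
#' @return `regions` with, per track `T`, columns `T_labels`
#'   (comma-separated unique labels, "" if none) and `T_bp` (total overlap
#'   bases, double-counting overlapping track intervals).
#' @export
annotate_regions <- function(regions, tracks) {
  stopifnot(is.data.frame(regions), is.list(tracks))
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list")
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(start = regions$start + 1,
                                                    end = regions$end))
  out <- regions
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    unknown <- setdiff(unique(tr$chrom), unique(regions$chrom))
    if (length(unknown))
      warning("track '", tn, "': skipping intervals on unknown chromosome(s) ",
              paste(unknown, collapse = ", "))
    tr_gr <- as_granges_track(tr[tr$chrom %in% regions$chrom, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(reg_gr, tr_gr, minoverlap = 1)
    ov <- GenomicRanges::pintersect(reg_gr[S4Vectors::queryHits(hits)],
                                    tr_gr[S4Vectors::subjectHits(hits)])
    labels <- rep("", nrow(regions))
    bp <- rep(0, nrow(regions))
    if (length(hits)) {
      lab_by <- split(as.character(tr_gr$label[S4Vectors::subjectHits(hits)]),
                      S4Vectors::queryHits(hits))
      bp_by <- split(GenomicRanges::width(ov), S4Vectors::queryHits(hits))
      idx <- as.integer(names(lab_by))
      labels[idx] <- vapply(lab_by, function(l)
        paste(unique(l), collapse = ","), "")
      bp[idx] <- vapply(bp_by, sum, 0)
    }
    out[[paste0(tn, "_labels")]] <- labels
    out[[paste0(tn, "_bp")]] <- bp
  }
  out
}

#' Classify annotated regions by repeat content
#'
#' The field's reading of high-frequency long-k-mer regions: they carry
#' either interspersed transposable elements (LINEs, mostly) or segmental
#' duplications, occasionally both.
#'
#' @param annotated Output of [annotate_regions()] that includes the TE
#'   and segdup tracks.
#' @param te_track,segdup_track Track names as used in `annotate_regions`.
#' @return `annotated` with a `class` column: `"TE-containing"`,
#'   `"segdup-overlapping"`, `"both"` or `"neither"`.
#' @export
classify_regions <- function(annotated, te_track = "TE",
                             segdup_track = "segdup") {
  for (tn in c(te_track, segdup_track)) {
    if (!paste0(tn, "_bp") %in% names(annotated))
      stop("annotation for track '", tn, "' missing; run annotate_regions ",
           "with both tracks first")
  }
  te <- annotated[[paste0(te_track, "_bp")]] > 0
  sd <- annotated[[paste0(segdup_track, "_bp")]] > 0
  annotated$class <- ifelse(te & sd, "both",
                     ifelse(te, "TE-containing",
                     ifelse(sd, "segdup-overlapping", "neither")))
  annotated
}

#' Read a BED-like interval track
#'
#' Tab-separated `chrom start end [label ...]`, 0-based half-open, no
#' header (header lines starting with `#` or `track` are skipped).
#'
#' @param path File path.
#' @return Data.frame `chrom`, `start`, `end`, `label`.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty interval track: ", path)
  f <- utils::read.table(text = lines, sep = "\t", fill = TRUE,
                         stringsAsFactors = FALSE)
  if (ncol(f) < 3) stop("track needs >= 3 columns (chrom, start, end): ", path)
  label <- if (ncol(f) >= 4) as.character(f[[4]]) else rep(".", nrow(f))
  label[is.na(label) | label == ""] <- "."
  data.frame(chrom = as.character(f[[1]]), start = f[[2]], end = f[[3]],
             label = label, stringsAsFactors = FALSE)
}

#' Write regions as BED (plus a readable table)
#'
#' The BED carries 0-based half-open coordinates; the TSV additionally
#' carries 1-based inclusive `start1`/`end1` columns for comparison with
#' browser-style tables.
#'
#' @param regions Region data.frame (possibly annotated/classified).
#' @param bed_path BED output path; a `.tsv` table is written when
#'   `tsv_path` is given.
#' @param tsv_path Optional TSV path.
#' @export
write_regions <- function(regions, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    tab <- regions
    tab$start1 <- regions$start + 1
    tab$end1 <- regions$end
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}
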