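load_pset <- function(fasta, mode, allowed_ids = NULL, lenient = FALSE) {
  rec <- read_fasta(fasta, allowed_ids = allowed_ids, lenient = lenient)
  if (mode == "gap-split") partition_on_gaps(rec) else partition_on_softmask(rec)
}

check_mode <- function(mode) {
  match.arg(mode, c("gap-split", "softmask-split"))
}

#' Run the mappability analysis end to end
#'
#' Partition, count at every k on the grid, compute p_ns / max f, and fit
#' the piecewise power laws. Writes `partitions.tsv`, `partitions.json`,
#' `mappability.tsv` (k, p_ns, p_ns_type, p_ns_with_gaps, max_f,
#' total_tokens, n_types) and `mappability_fits.json`.
#'
#' @param fasta Input genome FASTA.
#' @param outdir Output directory (created).
#' @param mode `"gap-split"` (all finished bases) or `"softmask-split"`
#'   (repeat-filtered).
#' @param k_grid Ascending k values.
#' @param segments Piecewise fit segments (k ranges); segments with fewer
#'   than 2 usable curve points are skipped with a warning.
#' @param allowed_ids,lenient Passed to [read_fasta()].
#' @param ... Passed to [count_kmers()].
#' @return Invisibly, list with `curve`, `fits`, `pset`.
#' @export
run_mappability <- function(fasta, outdir, mode = "gap-split",
                            k_grid = default_k_grid(),
                            segments = list(c(20, 80), c(200, 1000)),
                            allowed_ids = NULL, lenient = FALSE, ...) {
  mode <- check_mode(mode)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pset <- load_pset(fasta, mode, allowed_ids, lenient)
  write_partitions(pset, file.path(outdir, "partitions.tsv"))
  jsonlite::write_json(partition_summary(pset),
                       file.path(outdir, "partitions.json"),
                       auto_unbox = TRUE, digits = NA)
  curve <- mappability_curve(pset, k_grid, ...)
  write_tsv6(curve, file.path(outdir, "mappability.tsv"))
  fits <- list()
  for (seg in segments) {
    nm <- paste0("k", seg[1], "-", seg[2])
    res <- tryCatch(fit_piecewise(curve, list(seg))[[1]], error = function(e) {
      warning("skipping fit segment ", nm, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) fits[[nm]] <- res
  }
  if (length(fits))
    write_fits_json(fits, file.path(outdir, "mappability_fits.json"))
  invisible(list(curve = curve, fits = fits, pset = pset))
}

#' Run the distribution analyses at fixed k values
#'
#' For each k: the frequency distribution and its log-log slope over the
#' configured f range(s), the rank-frequency distribution, all three RFD
#' fits and the model-comparison table. Writes `fd_k<k>.tsv`,
#' `rfd_k<k>.tsv`, `fits_k<k>.json` and `rfd_comparison_k<k>.tsv`.
#'
#' @param fasta Input genome FASTA.
#' @param outdir Output directory.
#' @param k_set k values to analyse.
#' @param fd_ranges List of f ranges for the FD slope (fitted per range
#'   when enough occupied frequencies fall inside).
#' @inheritParams run_mappability
#' @return Invisibly, a per-k list of results.
#' @export
run_distributions <- function(fasta, outdir, mode = "gap-split",
                              k_set = c(30, 50, 150),
                              fd_ranges = list(c(3, 200)),
                              allowed_ids = NULL, lenient = FALSE, ...) {
  mode <- check_mode(mode)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pset <- load_pset(fasta, mode, allowed_ids, lenient)
  out <- list()
  for (k in k_set) {
    res <- tryCatch({
      tab <- count_kmers(pset, k, ...)
      fd <- frequency_distribution(tab)
      rfd <- rank_frequency(tab)
      stopifnot(sum(fd$f * fd$n_f) == tab$total_tokens)  # conservation
      write_tsv6(fd, file.path(outdir, sprintf("fd_k%d.tsv", k)))
      write_tsv6(rfd[, c("r", "f")],
                 file.path(outdir, sprintf("rfd_k%d.tsv", k)))
      fits <- list()
      for (fr in fd_ranges) {
        nm <- sprintf("fd_f%g-%g", fr[1], fr[2])
        fits[[nm]] <- tryCatch(fit_fd_slope(fd, fr), error = function(e) NULL)
      }
      cmp <- compare_rfd_fits(rfd)
      for (m in cmp$model) fits[[paste0("rfd_", m)]] <- attr(cmp, "fits")[[m]]
      write_fits_json(Filter(Negate(is.null), fits),
                      file.path(outdir, sprintf("fits_k%d.json", k)))
      write_tsv6(cmp, file.path(outdir, sprintf("rfd_comparison_k%d.tsv", k)))
      list(fd = fd, rfd = rfd, fits = fits, comparison = cmp)
    }, error = function(e) {
      warning("k = ", k, " failed: ", conditionMessage(e))
      NULL
    })
    out[[as.character(k)]] <- res
  }
  invisible(out)
}

#' Run the high-frequency region analysis
#'
#' Count at one (long) k, select types with f >= f_min, rescan the genome
#' for every occurrence, merge overlapping windows into regions, and, when
#' annotation tracks are given, annotate and classify them. Writes
#' `regions.bed`, `regions.tsv` and, with tracks, `regions_annotated.tsv`.
#'
#' @param fasta Input genome FASTA.
#' @param outdir Output directory.
#' @param k k-mer length (the published analysis used 1000).
#' @param f_min Inclusive frequency threshold (>= 2; published: 10).
#' @param max_gap Merge windows separated by at most this many bp.
#' @param te_track,segdup_track Optional BED-like paths (see
#'   [read_track()]); classification runs only when both are given.
#' @inheritParams run_mappability
#' @return Invisibly, list with `table`, `hfs`, `occurrences`, `regions`
#'   (annotated/classified when tracks were supplied).
#' @export
run_regions <- function(fasta, outdir, mode = "gap-split", k = 1000,
                        f_min = 10, max_gap = 0, te_track = NULL,
                        segdup_track = NULL, allowed_ids = NULL,
                        lenient = FALSE, ...) {
  mode <- check_mode(mode)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pset <- load_pset(fasta, mode, allowed_ids, lenient)
  tab <- count_kmers(pset, k, ...)
  hfs <- select_high_frequency(tab, f_min)
  occs <- locate_occurrences(pset, hfs)
  regions <- merge_windows(occs, k = k, max_gap = max_gap,
                           freqs = stats::setNames(hfs$f, hfs$kmer))
  if (nrow(regions) == 0)
    message("0 regions at k = ", k, ", f_min = ", f_min)
  tracks <- list()
  if (!is.null(te_track)) tracks$TE <- read_track(te_track)
  if (!is.null(segdup_track)) tracks$segdup <- read_track(segdup_track)
  annotated <- regions
  if (length(tracks) && nrow(regions)) {
    annotated <- annotate_regions(regions, tracks)
    if (all(c("TE", "segdup") %in% names(tracks))) {
      annotated <- classify_regions(annotated)
    } else {
      warning("need both TE and segdup tracks to classify; skipped")
    }
  } else if (!length(tracks)) {
    warning("no annotation tracks supplied; classification skipped")
  }
  write_regions(regions, file.path(outdir, "regions.bed"),
                file.path(outdir, "regions.tsv"))
  if (!identical(annotated, regions))
    utils::write.table(annotated, file.path(outdir, "regions_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(table = tab, hfs = hfs, occurrences = occs,
                 regions = annotated))
}

#' Simulate a study fixture (pipeline entry point)
#'
#' Thin wrapper over [simulate_study()] taking scalar arguments suited to
#' a command line.
#'
#' @param outdir Output directory.
#' @param seed RNG seed.
#' @param genome_length,mu,k_grid,f_min Forwarded to [sim_config()] /
#'   [simulate_study()].
#' @param ... Further [sim_config()] fields.
#' @return Invisibly, the [simulate_study()] result.
#' @export
run_simulate <- function(outdir, seed = 42, genome_length = 200000,
                         mu = 0.02, k_grid = c(20, 50, 100, 250),
                         f_min = 10, ...) {
  cfg <- sim_config(genome_length = genome_length, mu = mu, seed = seed, ...)
  simulate_study(cfg, k_grid = k_grid, outdir = outdir, f_min = f_min)
}

# TSVs are diff-stable: numeric columns at 6 significant digits
write_tsv6 <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x) & abs(x) < 1e15,
           format(x, scientific = FALSE, trim = TRUE),
           formatC(signif(x, 6), format = "g", digits = 6))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
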