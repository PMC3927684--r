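#' Simulation configuration
#'
#' The stated world the simulator emulates: a background sequence at
#' human-like GC, interspersed transposable-element (TE) families whose
#' genome copy numbers are long-tailed (truncated discrete power law, the
#' signature of ongoing duplication), per-copy point mutations, tandem
#' repeats, large exact segmental duplications, and N gaps, with inserted
#' TE/tandem copies soft-masked in lowercase.
#'
#' Defaults (units bp unless noted): 200 kb genome, GC 0.41, 8 TE families
#' of 300-3000 bp (Alu- to L1-scale), copy-number exponent alpha = 2.5
#' truncated at 50, per-copy substitution rate 0.02, two tandem arrays
#' (TG x 100, TTTA x 50 - microsatellite motifs seen in high-frequency
#' regions), one 10 kb segmental duplication in 2 exact copies, three N
#' gaps of 500-2000 bp.
#'
#' @param genome_length Genome length (bp); insertions replace background
#'   bases, so the length is exact.
#' @param gc_content Background GC fraction in (0, 1).
#' @param n_te_families Number of TE families.
#' @param te_length_range Bounds (bp) for family consensus lengths.
#' @param copy_alpha Power-law exponent (> 1) for family copy numbers.
#' @param copy_max Copy-number truncation (>= 1).
#' @param te_copy_numbers Optional integer vector (length
#'   `n_te_families`) of fixed per-family copy numbers, bypassing the
#'   power-law draw; used for truth-pinned fixtures.
#' @param mu Per-base substitution probability applied independently to
#'   each TE copy, in \[0, 1).
#' @param tandem_specs List of `list(unit =, n_units =, count =)`.
#' @param segdup_specs List of `list(length =, n_copies =)`.
#' @param n_gaps Number of N runs.
#' @param gap_length_range Bounds (bp) for gap lengths.
#' @param seed RNG seed; every output is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000,
                       gc_content = 0.41,
                       n_te_families = 8,
                       te_length_range = c(300, 3000),
                       copy_alpha = 2.5,
                       copy_max = 50,
                       te_copy_numbers = NULL,
                       mu = 0.02,
                       tandem_specs = list(
                         list(unit = "TG", n_units = 100, count = 2),
                         list(unit = "TTTA", n_units = 50, count = 2)),
                       segdup_specs = list(
                         list(length = 10000, n_copies = 2)),
                       n_gaps = 3,
                       gap_length_range = c(500, 2000),
                       seed = 42) {
  cfg <- list(genome_length = genome_length, gc_content = gc_content,
              n_te_families = n_te_families,
              te_length_range = te_length_range,
              copy_alpha = copy_alpha, copy_max = copy_max,
              te_copy_numbers = te_copy_numbers, mu = mu,
              tandem_specs = tandem_specs, segdup_specs = segdup_specs,
              n_gaps = n_gaps, gap_length_range = gap_length_range,
              seed = seed)
  stopifnot(genome_length > 0, gc_content > 0, gc_content < 1,
            n_te_families >= 0, copy_alpha > 1, copy_max >= 1,
            mu >= 0, mu < 1, n_gaps >= 0,
            is.null(te_copy_numbers) ||
              length(te_copy_numbers) == n_te_families)
  structure(cfg, class = "sim_config")
}

#' Random background sequence
#'
#' Independent draws with P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2.
#'
#' @param length Length in bp (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed Optional seed (set once here for standalone use; inside
#'   [build_genome()] the single build stream is used instead).
#' @return An ACGT string.
#' @export
generate_background <- function(length, gc, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Sample copy numbers from a truncated discrete power law
#'
#' P(c) proportional to c^(-alpha) on 1..c_max. Duplication dynamics
#' multiply copy numbers geometrically, which is what gives k-mer
#' frequency distributions their long tails; the exponent and truncation
#' are knobs, not claims about any particular genome.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param c_max Truncation (>= 1).
#' @param seed Optional seed.
#' @return Integer vector of length `n`.
#' @export
sample_copy_numbers <- function(n, alpha, c_max, seed = NULL) {
  if (alpha <= 1) stop("alpha must be > 1")
  if (c_max < 1) stop("c_max must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (c_max == 1) return(rep(1L, n))
  sample.int(c_max, n, replace = TRUE, prob = (1:c_max)^(-alpha))
}

mutate_seq <- function(s, mu) {
  if (mu <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < mu)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit], function(b) sample(alt[[b]], 1), "")
  }
  paste(ch, collapse = "")
}

# non-overlapping placement by uniform sampling over the free-interval
# list; >= 1 bp separation so each inserted feature remains its own
# lowercase/N run. Fails only when no gap can hold the feature.
place_features <- function(lengths, free) {
  starts <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    n_starts <- pmax(0, free$end - free$start - len + 2)
    if (sum(n_starts) == 0)
      stop("no room left for a feature of length ", len,
           "; lower the feature density in the sim_config")
    j <- sample.int(nrow(free), 1, prob = n_starts)
    s <- free$start[j] + sample.int(n_starts[j], 1) - 1
    e <- s + len - 1
    left <- data.frame(start = free$start[j], end = s - 2)
    right <- data.frame(start = e + 2, end = free$end[j])
    free <- rbind(free[-j, , drop = FALSE],
                  left[left$end >= left$start, , drop = FALSE],
                  right[right$end >= right$start, , drop = FALSE])
    starts[i] <- s
  }
  list(starts = starts, free = free)
}

#' Build a synthetic genome with truth tracks
#'
#' Background first; then each TE family's consensus is generated once and
#' inserted `c` times (c from the copy-number law), each copy carrying
#' i.i.d. substitutions at rate `mu` and lowercased; then tandem arrays
#' (lowercased) and exact segmental-duplication copies (uppercase, as real
#' segdups are not necessarily masked); N gaps last. Insertions replace
#' background (fixed genome length), features never overlap, and every
#' feature is recorded in a truth track (0-based half-open, chromosome
#' `chrS`).
#'
#' @param config A [sim_config()].
#' @return A `synthetic_genome`: `$records` (data.frame id/seq/length),
#'   `$truth` (list of data.frames `te`, `tandem`, `segdup`, `gap` with
#'   chrom/start/end/label), `$config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  ch <- strsplit(generate_background(L, config$gc_content), "",
                 fixed = TRUE)[[1]]
  free <- data.frame(start = 1, end = L)
  truth <- list()
  empty_truth <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), label = character(0),
                            stringsAsFactors = FALSE)
  tr_row <- function(s, len, label)
    data.frame(chrom = "chrS", start = s - 1, end = s - 1 + len,
               label = label, stringsAsFactors = FALSE)
  insert <- function(s, seq_str) {
    ch[s:(s + nchar(seq_str) - 1)] <<- strsplit(seq_str, "", fixed = TRUE)[[1]]
  }

  te_rows <- list()
  if (config$n_te_families > 0) {
    len_rng <- config$te_length_range[1]:config$te_length_range[2]
    fam_len <- if (length(len_rng) == 1) rep(len_rng, config$n_te_families)
               else sample(len_rng, config$n_te_families, replace = TRUE)
    copies <- if (!is.null(config$te_copy_numbers))
      as.integer(config$te_copy_numbers)
    else sample_copy_numbers(config$n_te_families, config$copy_alpha,
                             config$copy_max)
    for (i in seq_len(config$n_te_families)) {
      consensus <- generate_background(fam_len[i], config$gc_content)
      pl <- place_features(rep(fam_len[i], copies[i]), free)
      free <- pl$free
      for (s in pl$starts) {
        insert(s, tolower(mutate_seq(consensus, config$mu)))
        te_rows[[length(te_rows) + 1]] <-
          tr_row(s, fam_len[i], sprintf("TEfam%02d", i))
      }
    }
  }
  truth$te <- if (length(te_rows)) do.call(rbind, te_rows) else empty_truth

  td_rows <- list()
  for (spec in config$tandem_specs) {
    arr <- strrep(spec$unit, spec$n_units)
    pl <- place_features(rep(nchar(arr), spec$count), free)
    free <- pl$free
    for (s in pl$starts) {
      insert(s, tolower(arr))
      td_rows[[length(td_rows) + 1]] <-
        tr_row(s, nchar(arr), sprintf("tandem_%sx%d", spec$unit, spec$n_units))
    }
  }
  truth$tandem <- if (length(td_rows)) do.call(rbind, td_rows) else empty_truth

  sd_rows <- list()
  for (i in seq_along(config$segdup_specs)) {
    spec <- config$segdup_specs[[i]]
    src <- generate_background(spec$length, config$gc_content)
    pl <- place_features(rep(spec$length, spec$n_copies), free)
    free <- pl$free
    for (s in pl$starts) {
      insert(s, src)
      sd_rows[[length(sd_rows) + 1]] <-
        tr_row(s, spec$length, sprintf("segdup%02d", i))
    }
  }
  truth$segdup <- if (length(sd_rows)) do.call(rbind, sd_rows) else empty_truth

  gap_rows <- list()
  if (config$n_gaps > 0) {
    gap_rng <- config$gap_length_range[1]:config$gap_length_range[2]
    glen <- if (length(gap_rng) == 1) rep(gap_rng, config$n_gaps)
            else sample(gap_rng, config$n_gaps, replace = TRUE)
    pl <- place_features(glen, free)
    free <- pl$free
    for (i in seq_len(config$n_gaps)) {
      insert(pl$starts[i], strrep("N", glen[i]))
      gap_rows[[length(gap_rows) + 1]] <- tr_row(pl$starts[i], glen[i], "gap")
    }
  }
  truth$gap <- if (length(gap_rows)) do.call(rbind, gap_rows) else empty_truth

  truth <- lapply(truth, function(df) {
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  seq_str <- paste(ch, collapse = "")
  structure(list(records = data.frame(id = "chrS", seq = seq_str,
                                      length = nchar(seq_str),
                                      stringsAsFactors = FALSE),
                 truth = truth, config = config),
            class = "synthetic_genome")
}

#' Write genome records as FASTA (case and N preserved)
#'
#' @param records Data.frame with `id` and `seq` (e.g.
#'   `build_genome(cfg)$records`).
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

write_truth_bed <- function(df, path) {
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE), df$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a full study fixture
#'
#' Builds a genome, writes the FASTA, the per-class truth BEDs, the echoed
#' config, and a manifest of assertable expectations: minimum max(f) per k
#' implied by exact-copy features (always the tandem/segdup copies; TE
#' copies too when `mu = 0`), which feature classes must be recoverable at
#' a given `f_min`, and that p_ns is non-increasing over the k grid.
#'
#' @param config A [sim_config()].
#' @param k_grid k values the fixture is meant to be analysed at.
#' @param outdir Output directory (created if needed).
#' @param f_min Threshold used for the recoverability expectations.
#' @return Invisibly, a list with the genome object, file paths and the
#'   manifest.
#' @export
simulate_study <- function(config, k_grid = c(20, 50, 100, 250), outdir,
                           f_min = 10) {
  g <- build_genome(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(outdir, "genome.fasta")
  write_genome_fasta(g$records, fasta)
  beds <- list()
  for (cls in names(g$truth)) {
    beds[[cls]] <- file.path(outdir, paste0("truth_", cls, ".bed"))
    write_truth_bed(g$truth[[cls]], beds[[cls]])
  }
  exact <- data.frame(label = character(0), copies = numeric(0),
                      length = numeric(0))
  count_by <- function(df) {
    if (!nrow(df)) return(exact)
    agg <- stats::aggregate(start ~ label, df, length)
    len <- stats::aggregate(I(end - start) ~ label, df, max)
    data.frame(label = agg$label, copies = agg$start, length = len[[2]])
  }
  exact <- rbind(count_by(g$truth$tandem), count_by(g$truth$segdup))
  if (config$mu == 0) exact <- rbind(exact, count_by(g$truth$te))
  min_max_f <- lapply(k_grid, function(k) {
    ok <- exact$length >= k
    list(k = k, min_max_f = if (any(ok)) max(exact$copies[ok]) else 1)
  })
  recoverable <- exact$label[exact$copies >= f_min]
  manifest <- list(genome_length = config$genome_length, seed = config$seed,
                   mu = config$mu, k_grid = k_grid, f_min = f_min,
                   p_ns_non_increasing = TRUE, min_max_f = min_max_f,
                   recoverable_at_f_min = recoverable)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = g, fasta = fasta, truth_beds = beds,
                 manifest = manifest))
}
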