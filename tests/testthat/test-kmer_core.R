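test_that("reverse complement and canonical form match hand values and oracle", {
  expect_equal(reverse_complement("AAGC"), "GCTT")
  expect_equal(reverse_complement("AT"), "AT")
  expect_equal(reverse_complement("GGGGGGAACAGCGACAC"), "GTGTCGCTGTTCCCCCC")
  expect_error(reverse_complement("ACNT"), "non-ACGT")

  expect_equal(canonical_kmer(c("AAGC", "TTTT", "GAT")),
               c("AAGC", "AAAA", "ATC"))

  set.seed(1)
  rand <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), TRUE), collapse = ""),
    "")
  expect_equal(reverse_complement(rand), oracle_revcomp(rand))
  expect_equal(canonical_kmer(rand), oracle_canonical(rand))
  # a type and its reverse complement share one canonical form
  expect_equal(canonical_kmer(reverse_complement(rand)), canonical_kmer(rand))
})

test_that("k-mer type-space size matches brute-force enumeration", {
  for (k in 1:8) {
    all_k <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k)))
    expect_equal(kmer_type_count(k), length(unique(oracle_canonical(all_k))),
                 info = paste("k =", k))
  }
  expect_equal(kmer_type_count(17), 8589934592)
  expect_equal(kmer_type_count(2, exact = TRUE), "10")
  expect_equal(kmer_type_count(17, exact = TRUE), "8589934592")
  # exact decimal string agrees with 2^(2k-1) + 2^(k-1) for even k
  expect_equal(kmer_type_count(20, exact = TRUE),
               format(2^39 + 2^19, scientific = FALSE))
  expect_error(kmer_type_count(0), "k must be")
})

test_that("minimal k covering a genome size", {
  expect_equal(min_k_unique(1), 1L)
  expect_equal(min_k_unique(10), 2L)   # count(1) = 2 < 10 <= count(2) = 10
  expect_equal(min_k_unique(3e9), 17L)
  expect_error(min_k_unique(0), "genome_size")
})

test_that("counting matches hand examples and respects partition boundaries", {
  t1 <- count_kmers("AAAA", 2)
  expect_equal(t1$kmer, "AA")
  expect_equal(t1$count, 3)
  expect_equal(t1$total_tokens, 3)

  t2 <- count_kmers("ACGT", 2)
  expect_same_table(t2, list(kmer = c("AC", "CG"), count = c(2, 1),
                             total_tokens = 3))

  # k-mers never span partitions; short partitions contribute nothing
  t3 <- count_kmers(c("ACG", "GT"), 3)
  expect_equal(t3$kmer, "ACG")
  expect_equal(t3$total_tokens, 1)

  expect_warning(t4 <- count_kmers("ACG", 10), "exceeds every partition")
  expect_equal(t4$n_types, 0)
  expect_equal(t4$total_tokens, 0)
})

test_that("disk-bucketed counting equals in-memory counting and the oracle", {
  set.seed(7)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), "")
  for (k in c(2, 9, 33)) {
    orc <- oracle_count(seqs, k)
    mem <- count_kmers(seqs, k, strategy = "memory")
    expect_same_table(mem, orc)
    for (nb in c(1, 4)) {
      dsk <- count_kmers(seqs, k, strategy = "disk", n_buckets = nb)
      expect_identical(dsk$kmer, mem$kmer)
      expect_equal(dsk$count, mem$count)
      expect_equal(dsk$total_tokens, mem$total_tokens)
    }
  }
})

test_that("non-singleton proportions at token and type level", {
  one <- count_kmers("AAAA", 3)          # {AAA: 2}
  expect_equal(non_singleton_proportion(one), 1)
  expect_equal(non_singleton_proportion(one, "type"), 1)

  t2 <- count_kmers("ACGT", 2)
  expect_equal(non_singleton_proportion(t2), 2 / 3)
  expect_equal(non_singleton_proportion(t2, "type"), 1 / 2)

  empty <- suppressWarnings(count_kmers("ACG", 10))
  expect_error(non_singleton_proportion(empty), "empty")

  # token-level >= type-level on arbitrary tables (non-singleton types
  # carry at least two tokens each)
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE, prob = c(4, 1, 1, 2)),
               collapse = "")
    tab <- count_kmers(s, 4)
    expect_gte(non_singleton_proportion(tab, "token"),
               non_singleton_proportion(tab, "type"))
  }
})

test_that("unfinished-as-non-singleton variant counts windows over N", {
  # note GT would collapse onto AC as one canonical type, so use GA
  ps <- partition_strings("ACNGA")
  tab <- count_kmers(ps, 2)
  # finished tokens AC and GA are singleton types; 4 windows per chromosome
  expect_equal(non_singleton_with_gaps(tab, ps, 2), 0.5)

  # without any N the variant reduces to the plain token proportion
  ps2 <- partition_strings("ACGTACGT")
  tab2 <- count_kmers(ps2, 2)
  expect_equal(non_singleton_with_gaps(tab2, ps2, 2),
               non_singleton_proportion(tab2))
  expect_error(non_singleton_with_gaps(tab2, partition_strings("acgt",
    mode = "softmask-split"), 2), "gap-split")
})

test_that("max frequency reports the lexicographically smallest exemplar", {
  tab <- count_kmers(c("AAA", "AAA", "CAC"), 2)  # AA:2 each-> {AA:4?}
  mf <- max_frequency(tab)
  expect_equal(mf$f, max(tab$count))
  # construct an explicit tie: GG->CC canonical CC, AA  ("AAA","GGG")
  tie <- count_kmers(c("AAA", "GGG"), 2)         # AA:2, CC:2
  expect_equal(max_frequency(tie), list(f = 2, kmer = "AA"))
})

test_that("mappability curve is well-formed on degenerate and repeat inputs", {
  # a homopolymer partition is a single repeated type: p_ns = 1 for k < L
  homo <- partition_strings(strrep("A", 50))
  mc <- mappability_curve(homo, c(5, 20, 49))
  expect_equal(mc$p_ns, c(1, 1, 1))
  expect_equal(mc$max_f, 50 - c(5, 20, 49) + 1)

  # all partitions shorter than every k: rows reported as missing
  short <- partition_strings(c("ACGT", "GGTA"))
  expect_warning(mappability_curve(short, c(10)), "no tokens")
  mc2 <- suppressWarnings(mappability_curve(short, c(10, 20)))
  expect_true(all(is.na(mc2$p_ns)))
  expect_equal(mc2$total_tokens, c(0, 0))

  expect_error(mappability_curve(homo, c(20, 10)), "ascending")
})

test_that("counting is strand-invariant on a synthetic genome", {
  ps <- fix_small()$pset
  fwd <- count_kmers(ps, 21)
  rev <- count_kmers(reverse_complement(ps$partitions$seq), 21)
  expect_identical(fwd$kmer, rev$kmer)
  expect_equal(fwd$count, rev$count)
  expect_equal(fwd$total_tokens, rev$total_tokens)
})

test_that("count table TSV/JSON serialization is faithful", {
  tab <- count_kmers("ACGTACGTTT", 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, tsv)
  back <- read.delim(tsv, colClasses = c("character", "numeric"))
  expect_equal(back$kmer, tab$kmer)
  expect_equal(back$f, tab$count)
  side <- jsonlite::read_json(paste0(tsv, ".json"))
  expect_equal(side$total_tokens, tab$total_tokens)
  expect_equal(side$n_types, tab$n_types)
})
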