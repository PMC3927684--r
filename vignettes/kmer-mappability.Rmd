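---
title: "Methods: genome mappability from canonical k-mer spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome mappability from canonical k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmermap)
```

## The model

A length-k window of a reference genome stands in for a sequencing read.
Two windows that are reverse complements of each other are the same
**k-mer type**; the type's representative (its *canonical* form) is the
lexicographically smaller of the pair under A < C < G < T. The number of
occurrences ("tokens") of a type is its frequency f. A type with f = 1
is a singleton: a read with that sequence aligns to exactly one place.
Mappability at read length k is therefore summarised by the
**token-level non-singleton proportion**

$$p_{ns}(k) = \frac{\sum_{f>1} f\,n(f)}{\sum_f f\,n(f)},$$

the probability that a read drawn uniformly from the finished genome
cannot be uniquely placed. The type-level variant
$\sum_{f>1} n(f) / \sum_f n(f)$ is exposed for sensitivity analysis;
token level is the default because it is the read's-eye view. Token
level always dominates type level, since each non-singleton type
contributes at least two tokens.

The closed-form size of the type space is $4^k/2$ for odd k and
$(4^k + 2^k)/2$ for even k — the $2^k$ term counts reverse-complement
palindromes, which pair with themselves and exist only at even k.
`min_k_unique(3e9)` scans this formula and returns 17: below 17 bp no
human-sized sequence can avoid repeats, making 17 a hard lower bound
(and, in practice, a wild underestimate) of the read length needed for
unique alignment.

Two genome partitionings bracket the analysis. **Gap-split** cuts each
chromosome at runs of N (unfinished sequence) and uppercases what
remains: the all-inclusive analysis. **Softmask-split** additionally
cuts at lowercase (RepeatMasker-style soft-masked) runs: the
repeat-filtered analysis. Windows never span a partition boundary, so
every token lies entirely in finished (and, in the second mode,
unmasked) sequence. The gap-split mode also supports a pessimistic
variant, `non_singleton_with_gaps`, in which every per-chromosome
window position that is not a finished token counts as non-singleton —
reads from unfinished sequence can never be uniquely mapped. We count
windows per chromosome as length − k + 1 including those overlapping N;
the alternative per-base accounting differs only at gap margins and is
not exposed.

An open choice in gap-split mode is whether soft-masked lowercase bases
are kept. We keep them (uppercased): the all-inclusive series is meant
to describe all finished base pairs, and masking is a property of an
annotation program, not of the sequence.

## Counting engine

Counting is exact, strand-collapsed and deterministic. Two strategies
produce identical tables:

- **memory**: one hash table of canonical strings (C++,
  `std::unordered_map`), RAM proportional to the number of distinct
  types times k.
- **disk**: two passes in the style of disk-based k-mer counters. Pass
  one streams every canonical token to one of `n_buckets` spill files,
  addressed by a 64-bit FNV-1a hash of the canonical string; pass two
  counts each bucket independently and concatenates. Since a type's
  tokens all land in one bucket, the result is exactly the in-memory
  table while peak RAM is roughly 1/n_buckets of the type space.

`strategy = "auto"` picks disk when a coarse estimate
(windows × (k + 64) bytes) exceeds `max_ram`. Equality of the two
strategies, for several k and bucket counts, against an independent
pure-R dictionary oracle, is part of the test suite.

Keys are the canonical strings themselves rather than a 2-bit packed
encoding. Byte order on {A,C,G,T} equals the required lexicographic
order, any k is representable, and at the scales this package targets
(desk-scale genomes; the disk engine for anything larger) the ~4x
memory premium buys substantial simplicity. A packed-key engine would
be a drop-in replacement behind the same interface if ever needed.

Ties and ordering are fixed everywhere to make outputs byte-stable:
count tables are sorted by canonical k-mer (byte order); the
rank-frequency distribution breaks frequency ties by canonical k-mer,
giving distinct consecutive ranks 1..n_types (ordinal Zipf ranks, and
the Weibull fit needs max(r) = n_types); `max_frequency` reports the
lexicographically smallest exemplar.

## Distributions and fits

All regressions are ordinary least squares via `lm`, unweighted, on
transformed variables — plain regression, not maximum-likelihood
power-law estimation, which is deliberately out of scope.

- **Piecewise power law on p_ns(k)**: `log10 p_ns = a + b log10 k`,
  fitted separately on k segments (shipped defaults 20–80 and
  200–1000, leaving the 80–200 transition unfitted: the decay is
  visibly not a single power law, steep at short k and flat past
  ~200 bp). `extrapolate_powerlaw` predicts beyond the fitted range
  (e.g. 10 kb reads); `solve_unit_frequency` returns
  `10^(−a/b)`, the k where a decaying fit (e.g. max f vs k) reaches 1.
  Extrapolation assumes the fitted regime continues — the package
  computes it, the caller owns the assumption.
- **FD slope**: `log10 n(f) = a + b log10 f` over occupied frequencies
  within an f range; no zero bins, no smoothing, no binning. The slope
  steepens (grows more negative) as k approaches typical repeat-element
  lengths, so it is a scale-dependent summary, not a universal exponent;
  the f range is a parameter with no default beyond what the caller
  chooses.
- **Rank-frequency fits**: three two-to-three-coefficient linear
  models for concave ("Z"-shaped) log-log Zipf curves — Weibull
  `log f ~ log(log((max(r)+1)/r))`, quadratic-logarithmic
  `log f ~ log r + (log r)^2`, and the reverse Beta
  `log r ~ log f + log(max(f)+1−f)`, the Beta rank function with the
  roles of f and r exchanged. Natural logs throughout these three (the
  regression literature they come from writes plain log; coefficients
  are base-dependent, so the base is fixed and documented), base-10 for
  the power-law fits. At f = max(f) the reverse-Beta term log(1) = 0 is
  finite and the pair is retained.
- **Model comparison**: the three fits do not share a response space
  (reverse Beta regresses log r). `compare_rfd_fits` reports each RSS
  in its own space and, for ranking, the RMS error of predicted vs
  observed log f at the observed ranks, inverting the reverse-Beta
  prediction by monotone bisection on f ∈ (0, max f + 1); a
  non-monotone predicted relation is reported as NA rather than an
  error. The RMS column is this package's construction for putting the
  models on one footing, and is flagged as such.

## High-frequency regions

Types with f ≥ f_min (f_min ≥ 2; the headline analysis used k = 1000,
f_min = 10) are located by an exact canonical rescan of the partitioned
genome: since the k-mers were extracted from the same assembly with
zero mismatches, exact matching finds every site an aligner would, with
no external alignment tool and no heuristics. Occurrences are recorded
at the forward-strand window start regardless of matching strand.

Windows [pos, pos + k) on one chromosome merge when they overlap or
abut within `max_gap` (default 0). The merging rule that produced the
published region count is not stated anywhere we can follow, so plain
overlap/abutment is the default and `max_gap` is a sensitivity knob.
Region records carry the distinct-type count, occurrence count, max f
inside, and the end-to-start distance to the left neighbour (the other
plausible reading, start-to-start, is not used; the choice is
documented here and in the field the distance-to-neighbour column is
descriptive only). Interval algebra (merge, overlap, intersection
widths) is delegated to IRanges/GenomicRanges.

Annotation takes BED-like interval tracks (0-based half-open); any
positive-length intersection is a hit — touching half-open intervals
are not. Classification against a TE track and a segmental-duplication
track yields `TE-containing`, `segdup-overlapping`, `both` or
`neither`; `neither` is a flag for manual review (in the synthetic
world, tandem arrays land there by design).

## The synthetic world

The simulator generates what the analysis assumes about real genomes:

| knob | default | why |
|---|---|---|
| genome_length | 200 kb | large enough for k = 1000 analysis in seconds |
| gc_content | 0.41 | human-like background composition |
| n_te_families | 8 | a handful of interspersed families |
| te_length_range | 300–3000 bp | Alu-scale to truncated-LINE-scale |
| copy_alpha | 2.5 | long-tailed copy numbers, P(c) ∝ c^−2.5, the observed FD-tail regime |
| copy_max | 50 | truncation keeping total TE mass placeable |
| mu | 0.02 | few-percent per-copy divergence, typical of TE families |
| tandem_specs | TG×100, TTTA×50 (×2 each) | microsatellite motifs seen in real high-frequency regions |
| segdup_specs | one 10 kb × 2 copies | segmental duplications are kb-scale, near-identical |
| n_gaps | 3 of 0.5–2 kb | interspersed unfinished runs |

Copy numbers follow a truncated discrete power law because duplication
dynamics multiply copies geometrically; the knobs are properties of the
fixture, not claims about any particular genome. Insertions replace
background bases (the genome length is exact, which keeps truth-track
bookkeeping trivial), features are placed without overlap by sampling
uniformly over the free-interval list with ≥ 1 bp separation (so each
inserted feature is exactly one lowercase or N run), and the mutation
model is substitution-only — exact-match counting is degraded by
substitutions just as by indels, and indels would complicate truth
coordinates for no test benefit. TE and tandem copies are lowercased
(soft-masking truth); segmental-duplication copies stay uppercase, as
real segdups are not necessarily masked; gaps are Ns. A single RNG
stream per build, seeded once from the config, makes every output a
pure function of the config; reproducibility under *partial* config
changes is not promised.

What a green test establishes: exact bookkeeping (conservation, strand
invariance, counter equivalence), correct recovery of planted structure
(copies of an element found and merged at the right coordinates), and
the qualitative distribution shapes the fits target (long FD tails,
concave RFDs, monotone p_ns decay). What it does not establish: any
genome-wide number for a real assembly — those require the real
reference as input, and every operation needed to reproduce them
(24-chromosome name filter included) is exposed, but the package ships
no external data.

Two fixture-level properties deserve their caveats. p_ns(k)
non-increasing in k is asserted on fixtures, not proved — boundary
effects can in principle break it, they just do not arise in these
worlds. The FD-slope steepening property is asserted on a many-family
fixture over k = 30–300, the regime where the f = 2–30 tail keeps
enough occupied frequencies for a meaningful regression; past the
longest element (k ≫ 1000 here) the tail collapses to a handful of
bins and the slope estimate is noise, which is itself the point the
property illustrates.

## Numerical and interface choices

- Coordinates are 0-based half-open everywhere (BED-compatible);
  human-readable region tables additionally carry 1-based inclusive
  columns.
- `kmer_type_count` returns numeric (exact to k = 26, double's 2^53
  limit) or an exact decimal string at any k via schoolbook big-integer
  doubling — no bignum dependency exists in the target environment.
- TSV outputs fix numerics at 6 significant digits for stable diffs;
  JSON keeps full precision.
- Characters outside {A,C,G,T,N, lowercase} are rejected by default; a
  lenient mode maps IUPAC ambiguity codes to N. Empty selections,
  empty tables and k longer than every partition are explicit errors
  or warnings, never silent empties (an empty table from an oversized
  k warns and reports zero tokens; curve rows at such k are NA).
- The pipeline entry points (`run_simulate`, `run_mappability`,
  `run_distributions`, `run_regions`) validate inputs before
  computing, write machine-readable outputs per stage, and are fronted
  by a thin Rscript CLI (`inst/cli/kmermap.R`); partition tables,
  count-table TSVs and annotation TSVs are emitted by the same runs
  rather than by separate subcommands.

## Known limitations

- Exact matching only: no mismatch-tolerant counting, no
  sequencing-error or SNP model, no paired-end mappability — the
  statistics describe the reference itself.
- OLS on log-transformed data has no error model; no bootstrap CIs or
  information-criterion model selection are offered.
- The disk engine bounds memory but not intermediate disk (spill files
  hold one line per token); `workdir` must hold roughly the token
  stream.
- The simulator's TE families are random sequences, not consensus
  libraries with subfamily phylogenies; fixture realism is structural
  (copy-number tails, masking, gaps), not sequence-level.
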