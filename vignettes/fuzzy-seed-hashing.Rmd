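---
title: "Fuzzy seed matching with SimHash seed hashing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy seed matching with SimHash seed hashing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyseed)
```

## The problem

Seed-and-chain methods find similarities between nucleotide sequences by
extracting short *seeds*, hashing them, and matching seeds between sequences
with a single hash-table lookup. Conventional mappers use low-collision hash
functions, so only *exactly* identical seeds collide: one sequencing error or
variant inside a seed destroys the match. `fuzzyseed` implements a
locality-sensitive alternative: seeds are converted to multisets of item
hashes and hashed with SimHash, a per-bit majority vote, so *highly similar*
seeds tend to receive the *same* hash value and are found by the same single
lookup — a fuzzy seed match. Everything needed to exercise the idea end to
end is included: minimizer and strobemer-style seeding, a seed index with
repeat filtering, co-linear anchor chaining to PAF records, FASTA/FASTQ
input, a read simulator with truth intervals, and the evaluation experiments
used in the tests.

## The hashing core

A k-mer is packed 2 bits per base (A=0, C=1, G=2, T=3, first base most
significant) and hashed with a seedable splitmix64-style finalizer — an
invertible 64-bit mixing function truncated to the low `b` bits. This is the
*base hash*: it plays two roles, as the low-collision baseline scheme and as
the generator of SimHash items.

SimHash maps a multiset of `b`-bit items to one `b`-bit value. For bit
position `t`, a counter accumulates +1 for every item with bit `t` set and
−1 for every item with it clear (multiplicity counts); the output bit is 1
exactly when the counter is positive, with ties decoding to 0. A few changed
items rarely overturn per-bit majorities, so similar multisets usually hash
identically. The tie rule matters: it breaks complement symmetry at even
multiset sizes, which is why the complement-symmetry test in the suite uses
odd sizes only.

Two conventions are fixed for bit-exact reproducibility: bit `t = 0` is the
least-significant bit everywhere, and hash values cross the R boundary as
fixed-width lowercase hex strings of `ceiling(b/4)` characters (R doubles
cannot represent 64-bit integers exactly; ordering on these strings matches
numeric ordering). The hot paths — packing, hashing, voting, seeding,
chaining — are compiled C++.

```{r simhash-demo}
cfg <- simhash_config(b = 16, hash_seed = 1)
items <- base_hash(pack_kmer("ACGTACGTACG")$value + 0:4, cfg)
simhash(items, cfg)
counter_vector(items, cfg)
```

## From sequences to seeds

Three seeding modes share one surface, `seed_stream()`:

* **baseline** — classical minimizers: in every window of `w` consecutive
  canonical L-mers, the word with the smallest base hash is selected
  (leftmost on ties; consecutive windows sharing a minimum emit it once).
  Palindromic words are skipped — their strand is ambiguous — and default
  word lengths are odd so none occur. Windows containing ambiguous bases
  contribute only their packable words.
* **blend_i** — substitution-sensitive fuzzy hashing. Each L-mer's hash is
  the SimHash of the base hashes of its `n` overlapping sub-k-mers of
  length `k' = L − n + 1`, read on the canonical orientation of the L-mer
  (so seeds are strand-independent). The SimHash value itself is the
  minimizer selection value: the fuzzy hash *replaces* the hash function
  inside the seeding scheme rather than being bolted on after selection.
  One substitution perturbs at most `min(k', n)` of the `n` items, so a
  mutated seed often keeps its hash.
* **blend_s** — indel-tolerant strobemer-style seeding. Minimizers of
  length `k` are computed first; each minimizer starts a seed that links
  the next `n − 1` minimizers *sharing its orientation*, and the seed's
  hash is the SimHash of the `n` linked k-mer hashes. Because SimHash is
  order-invariant, a whole strobe may mismatch — or indels may shift the
  gaps between strobes — without changing the hash.

On strobe linking, the design was genuinely open. Restricting seeds to runs
of *strictly consecutive* minimizers that all share one strand and skipping
any interrupted run is the simplest rule, but minimizer strands are
approximately fair coin flips, so it silently discards a `2^-(n-1)` fraction
of candidate seeds — at `n = 5` and `w = 50` that leaves roughly four or
five seeds on a 2 kb read, too few to chain reliably (about a third of
error-free reads fail to map). Passing over opposite-strand minimizers when
assembling the run keeps the same-strand correctness rule, keeps `n` votes
per seed, and restores a seed at essentially every minimizer. That is the
rule implemented; runs are abandoned only when too few same-strand
minimizers remain downstream. Both query and target apply the same rule to
the same minimizer stream, so exact matches are never lost.

Defaults echo the two regimes the schemes target: `blend_i` with `L = 15,
n = 5, w = 10` for erroneous long reads, and `blend_s` with `k = 19, n = 5,
w = 50` for accurate HiFi-style reads, where fuzzy matching tolerates much
sparser sampling.

## Index, anchors, chains

`build_index()` stores `(seq_id, start, span, strand)` records — never
sequence text — in a hash table keyed by seed hash. A query seed retrieves
every exact *and* fuzzy match with one lookup; no neighborhood of keys is
ever scanned. Keys occurring more than `max_occ = 1000` times are dropped
after insertion (repeat masking), which bounds anchor collection on
repetitive targets.

Anchors on the same target and relative orientation are chained by dynamic
programming maximizing `sum(spans) − sum(|Δq − Δt|)`, with transitions
required to be strictly monotone in both coordinates and bounded by
`max_gap = 5000`. The linear diagonal-drift gap cost was chosen over a
concave cost deliberately: it admits an exhaustive-enumeration oracle, and
the test suite verifies the DP against that oracle on a thousand random
instances. Chains are extracted best-score-first with anchor consumption;
chains scoring under 40 or with fewer than 3 anchors are dropped. Mapping
quality is `floor(40 (1 − s2/s1))` clamped to `[0, 60]`, where `s2` is the
best score among the query's other chains — deterministic and monotone in
score separation.

PAF records extend the chained interval along the chain diagonal to the
sequence ends (`extend = FALSE` disables this). This is the usual
overlap-extension convention of assembly-oriented overlappers, and it is
what makes reported intervals comparable across window lengths: with
`w = 50` the first and last seeds of a read sit ~25 bp inside it on
average, which would otherwise cap apparent coverage below the chain's real
extent.

## A worked overlap

```{r overlap-demo}
g <- random_genome(20000, rng_seed = 2)
sim <- simulate_reads(g, coverage = 5, read_len_mean = 1500,
                      read_len_sd = 150,
                      profile = mutation_profile(0.02, 0.005, 0.005),
                      rng_seed = 3)
paf <- overlap_sequences(sim$reads, seeding_params("blend_i"),
                         simhash_config(b = 64))
head(paf[, 1:12], 3)
unlist(overlap_recall(sim$truth, paf, min_true_overlap = 500)[
  c("recall", "precision")])
```

## What the simulator does and does not emulate

`random_genome()` draws i.i.d. bases at a chosen GC fraction;
`simulate_reads()` draws uniform start positions, truncated-normal lengths,
uniform strands, and applies per-base substitution/insertion/deletion edits
with recorded truth coordinates. This captures the coverage geometry and
error regimes that seeding and chaining react to, but deliberately not
repeat structure, error clustering, homopolymer bias, or realistic
qualities. Passing tests therefore demonstrate the mechanism's behavior
under clean, known conditions — not performance on real genomes, where
repeats dominate the difficulty. For collision studies, `tandem_genome()`
constructs the repeat structure explicitly: tandem copies of one unit with
per-copy substitutions, which makes near-identical seed pairs reachable by
design.

## Evaluation experiments and numerical choices

`uplift_experiment()` measures the probability that a word pair at
substitution distance `d` receives the same hash under the fuzzy scheme
versus the baseline. Words are hashed on their forward orientation as
written: after a mutation, the canonical orientation of a word can flip,
and hashing canonically would mix strand-decision noise into what is meant
to be a pure comparison of hash schemes. At `L = 15, n = 5`, only
substitutions near the word ends leave most items intact, so same-hash
rates are small in absolute terms (about `2 × 10^-4` at `b = 32`) and grow
as the output width shrinks or the neighbor count rises — the neighbor
monotonicity experiment runs at `b = 16` where rates are comfortably
measurable.

`collision_histogram()` mirrors the collision-analysis methodology:
enumerate all seeds, bucket by hash, and tabulate edit distances between
*distinct* non-identical subsequences sharing a bucket. Two choices matter.
First, pairs are deduplicated by text: on tandem genomes, copy number would
otherwise inflate every count quadratically with copy-number noise to
match. Second, the default width for these experiments is `b = 16`, chosen
analytically: at `b = 64` neither scheme produces observable collisions at
the 100 kb scale (a changed item flips each output bit with probability
~0.19, and `0.81^64` is ~10^-6), while 2^16 buckets against ~2 × 10^4
seeds make both chance collisions (the baseline's tail) and fuzzy
collisions (the SimHash head) visible in one histogram. All-pairs edit
distance inside large buckets is quadratic, so beyond `max_pairs` a seeded
uniform subsample is tallied and flagged.

Degenerate inputs are handled explicitly: empty item multisets and
ambiguous-base words signal errors; palindromic words are skipped during
seeding; `d = 0` in the uplift experiment is allowed as a calibration point
(both rates are exactly 1); an empty PAF yields recall and precision 0 with
a `no_records` flag rather than NaN.

## Problem sizes used by the checks

The acceptance-style tests and `scripts/acceptance.R` run at desk scale,
chosen so every check completes in seconds to a couple of minutes: 10^4
random multisets for the SimHash oracle; a 100 kb genome with 200
error-free 2 kb reads for exact-match completeness; 10^4 word pairs for the
uplift experiment; a 100 kb tandem genome (1 kb unit, 100 copies, one
substitution per copy) for collision skew; 10^3 random instances of at most
12 anchors for the chaining oracle; and a 50 kb genome at 20× coverage with
5%/1%/1% substitution/insertion/deletion rates for overlap recall. These
sizes are the package's stated study conditions; they are not estimates of
throughput on real datasets.

## Limitations

The implementation is single-threaded by design (`-t` is accepted for
interface compatibility); the serial path is the correctness baseline.
Chaining uses the linear drift cost, not a concave minimap2-style cost, so
very long indels inside one chain are penalized more aggressively than a
production mapper would. There is no base-level alignment, no CIGAR or SAM
output, and no multi-part index for genomes that exceed memory. Hash
widths below 64 bits trade specificity for fuzzy sensitivity; the defaults
(`b = 64` for mapping and overlapping, `b = 16` for collision studies) sit
at the two ends of that trade-off deliberately.
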