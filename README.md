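# fuzzyseed

Finding similarities between genomic sequences usually starts with *seeds*:
short subsequences whose hash values are matched between sequences with a
single hash-table lookup. Conventional low-collision hash functions make
that lookup find only *exactly* identical seeds — one sequencing error or
variant inside a seed breaks the match, forcing mappers to sample densely
and chain aggressively. `fuzzyseed` implements a locality-sensitive seed
hashing mechanism in which *highly similar* seeds receive the *same* hash
value, so both exact and fuzzy seed matches fall out of the same single
lookup. It is aimed at people studying seeding and sketching schemes for
long-read overlapping and mapping, and at anyone who wants a compact,
fully-tested reference implementation of SimHash-based fuzzy seeding.

## The mechanism

A seed is converted to a multiset of `b`-bit item hashes and compressed to
one `b`-bit value by **SimHash** (per-bit majority voting). For bit `t`,

```
c_t = #{items with bit t = 1} − #{items with bit t = 0}
h_t = 1 if c_t > 0, else 0        (ties → 0)
```

A few changed items rarely overturn the majorities, so similar item
multisets hash identically. Two sequence-to-set conversions are provided:

* **blend_i** (substitution-sensitive): the items of an `L`-mer are the
  base hashes of its `n` overlapping sub-k-mers of length `L − n + 1`;
  a substitution perturbs at most `min(L − n + 1, n)` items.
* **blend_s** (indel-tolerant): minimizers of length `k` are linked
  strobemer-style into seeds of `n` same-orientation k-mers; the items are
  the `n` linked k-mer hashes, so whole strobes may mismatch and the gaps
  between them may stretch.

Item hashes come from a seedable invertible 64-bit mixing finalizer — the
same low-collision hash that serves as the exact-matching **baseline**
mode. Seeds are sampled with minimizers (minimum hash per window of `w`
words, and in `blend_i` the SimHash value itself is the selection value).
Matches are grouped per target, chained by a dynamic program maximizing
`Σ spans − Σ |Δq − Δt|`, and reported as 12-column PAF.

## A worked example

Simulate a 20 kb genome, sequence it to 5× with 2%/0.5%/0.5%
substitution/insertion/deletion errors, and find all-vs-all read overlaps
with fuzzy seeds:

```r
library(fuzzyseed)

g   <- random_genome(20000, rng_seed = 2)
sim <- simulate_reads(g, coverage = 5, read_len_mean = 1500,
                      read_len_sd = 150,
                      profile = mutation_profile(0.02, 0.005, 0.005),
                      rng_seed = 3)
paf <- overlap_sequences(sim$reads, seeding_params("blend_i"),
                         simhash_config(b = 64))
head(paf[, 1:12], 3)
#>       qname qlen qstart qend strand     tname tlen tstart tend nmatch alen mapq
#> 1 read00001 1358      0 1260      - read00058 1702      0 1262   1575 1262    7
#> 2 read00001 1358      0 1358      + read00014 1532     42 1395   1305 1358    0
#> 3 read00001 1358     81 1358      + read00063 1538      0 1276   1260 1277    0

unlist(overlap_recall(sim$truth, paf, min_true_overlap = 500)[
  c("recall", "precision")])
#>    recall precision
#> 1.0000000 0.6768802
```

Each PAF row is one chained overlap: read `read00001` overlaps
`read00058` on opposite strands over ~1.26 kb with 1575 anchor bases, and
every true ≥500 bp overlap in the simulation was recovered (recall 1.0;
precision counts shorter-than-500 bp overlaps as false, hence < 1).

The fuzzy uplift is visible directly on word pairs one substitution apart —
the baseline never matches them, SimHash hashing sometimes does:

```r
up <- uplift_experiment(10000, 15, 1, cfg = simhash_config(b = 32),
                        rng_seed = 42)
c(blend = up$blend_rate, baseline = up$baseline_rate)
#>    blend baseline
#>    1e-04    0e+00
```

A command-line interface is installed under the package's `exec/`
directory with `index`, `map`, `overlap` and `collide` subcommands:

```sh
fuzzyseed=$(Rscript -e 'cat(system.file("exec", "fuzzyseed", package = "fuzzyseed"))')
$fuzzyseed index genome.fa --mode blend_i -o genome.idx.rds
$fuzzyseed map genome.idx.rds reads.fq --mode blend_i -o mapped.paf
$fuzzyseed overlap reads.fq --mode blend_s -o overlaps.paf
$fuzzyseed collide genome.fa -b 16 -o collisions.tsv
```

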