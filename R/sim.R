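#' Mutation profile for the read simulator
#'
#' Per-base, mutually exclusive event probabilities: substitution to a
#' uniformly chosen different base, insertion of one random base after the
#' position, or deletion of the base. Rates must be non-negative and sum to
#' at most 1 (a sum of exactly 1 leaves no position unedited).
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities.
#' @param rng_seed Optional integer seed. When set, [mutate_seq()] draws its
#'   randomness under this seed (restoring the caller's RNG state); when
#'   `NULL`, it consumes the current RNG stream -- which is how
#'   [simulate_reads()] keeps all per-read randomness under one master seed.
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                             rng_seed = NULL) {
  if (sub_rate < 0 || ins_rate < 0 || del_rate < 0)
    stop("mutation rates must be non-negative")
  if (sub_rate + ins_rate + del_rate > 1)
    stop("sub_rate + ins_rate + del_rate must be <= 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, rng_seed = rng_seed),
            class = "mutation_profile")
}

BASES <- c("A", "C", "G", "T")

#' Generate a random genome sequence
#'
#' I.i.d. bases with `P(G) + P(C) = gc_fraction`, split evenly within each
#' pair; deterministic for a fixed seed.
#'
#' @param length Genome length in bases.
#' @param gc_fraction GC content in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @return One-row data.frame (`name`, `seq`, `qual = NA`) as from
#'   [read_sequences()].
#' @export
random_genome <- function(length, gc_fraction = 0.5, rng_seed = 1L) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  seq <- withr::with_seed(rng_seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
           (1 - gc_fraction) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  data.frame(name = "genome", seq = seq, qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate a tandem-repeat genome with per-copy substitutions
#'
#' Concatenates `n_copies` copies of one random unit, each copy carrying
#' `subs_per_copy` substitutions at random positions. This construction
#' makes fuzzy seed collisions reachable by design: seeds at the same
#' offset in different copies are near-identical, differing by the few
#' per-copy edits.
#'
#' @param unit_len Length of the repeat unit.
#' @param n_copies Number of tandem copies.
#' @param subs_per_copy Substitutions applied independently to each copy.
#' @param rng_seed Integer seed.
#' @return One-row data.frame (`name`, `seq`, `qual`).
#' @export
tandem_genome <- function(unit_len = 1000L, n_copies = 100L,
                          subs_per_copy = 1L, rng_seed = 1L) {
  seq <- withr::with_seed(rng_seed, {
    unit <- sample(BASES, unit_len, replace = TRUE)
    copies <- vapply(seq_len(n_copies), function(i) {
      u <- unit
      pos <- sample.int(unit_len, subs_per_copy)
      for (p in pos) u[p] <- sample(setdiff(BASES, u[p]), 1L)
      paste(u, collapse = "")
    }, character(1))
    paste(copies, collapse = "")
  })
  data.frame(name = "tandem", seq = seq, qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Mutate a sequence under a profile
#'
#' Applies the per-position event model of [mutation_profile()] and records
#' a truth list of edits with their 0-based original coordinates. The edit
#' distance between input and output never exceeds the number of recorded
#' edits.
#'
#' @param seq A nucleotide string.
#' @param profile A [mutation_profile()].
#' @return List with `seq` (mutated string) and `truth` (data.frame `pos`,
#'   `op` in sub/ins/del, `base`).
#' @export
mutate_seq <- function(seq, profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    m <- length(chars)
    if (m == 0L)
      return(list(seq = "", truth = data.frame(pos = integer(0),
                                               op = character(0),
                                               base = character(0),
                                               stringsAsFactors = FALSE)))
    u <- runif(m)
    s <- profile$sub_rate; i <- profile$ins_rate; d <- profile$del_rate
    ev <- ifelse(u < s, "sub", ifelse(u < s + i, "ins",
                 ifelse(u < s + i + d, "del", "none")))
    out <- chars
    subs <- which(ev == "sub")
    newbase <- character(length(subs))
    for (j in seq_along(subs)) {
      newbase[j] <- sample(setdiff(BASES, toupper(chars[subs[j]])), 1L)
      out[subs[j]] <- newbase[j]
    }
    ins <- which(ev == "ins")
    insbase <- if (length(ins)) sample(BASES, length(ins), replace = TRUE)
      else character(0)
    out[ins] <- paste0(chars[ins], insbase)
    del <- which(ev == "del")
    out[del] <- ""
    edits <- ev != "none"
    truth <- data.frame(pos = which(edits) - 1L, op = ev[edits],
                        base = rep(NA_character_, sum(edits)),
                        stringsAsFactors = FALSE)
    truth$base[truth$op == "sub"] <- newbase
    truth$base[truth$op == "ins"] <- insbase
    list(seq = paste(out, collapse = ""), truth = truth)
  }
  if (!is.null(profile$rng_seed)) withr::with_seed(profile$rng_seed, run())
  else run()
}

#' Simulate reads with truth intervals
#'
#' Uniform start positions, normal read lengths truncated to
#' `[100, genome length]`, uniform strand; each read is oriented (reverse
#' complemented for `-` strand) and then mutated under `profile`. Truth
#' records the genomic half-open interval and strand each read was drawn
#' from. Deterministic per `rng_seed`.
#'
#' @param genome One-row data.frame (`name`, `seq`) or a single string.
#' @param coverage Target sequencing depth; the read count is
#'   `ceiling(coverage * genome_len / read_len_mean)`.
#' @param read_len_mean,read_len_sd Normal length model parameters.
#' @param profile A [mutation_profile()] (its own `rng_seed` is ignored
#'   here; all randomness flows from `rng_seed`).
#' @param rng_seed Integer master seed.
#' @return List with `reads` (data.frame `name`, `seq`, `qual`) and `truth`
#'   (data.frame `name`, `seq_id`, `start`, `end`, `strand`).
#' @export
simulate_reads <- function(genome, coverage, read_len_mean = 2000,
                           read_len_sd = 200,
                           profile = mutation_profile(), rng_seed = 1L) {
  if (is.data.frame(genome)) {
    gseq <- genome$seq[1L]; gname <- genome$name[1L]
  } else {
    gseq <- genome; gname <- "genome"
  }
  glen <- nchar(gseq)
  stopifnot(coverage > 0, glen > read_len_mean)
  profile$rng_seed <- NULL
  withr::with_seed(rng_seed, {
    n_reads <- as.integer(ceiling(coverage * glen / read_len_mean))
    lens <- pmin(pmax(round(rnorm(n_reads, read_len_mean, read_len_sd)),
                      100L), glen)
    starts <- floor(runif(n_reads) * (glen - lens + 1))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    names <- sprintf("read%05d", seq_len(n_reads))
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- substr(gseq, starts[i] + 1L, starts[i] + lens[i])
      if (strands[i] == "-") s <- revcomp_seq(s)
      seqs[i] <- mutate_seq(s, profile)$seq
    }
    list(reads = data.frame(name = names, seq = seqs,
                            qual = vapply(nchar(seqs), function(n)
                              strrep("I", n), character(1)),
                            stringsAsFactors = FALSE),
         truth = data.frame(name = names, seq_id = gname,
                            start = as.integer(starts),
                            end = as.integer(starts + lens),
                            strand = strands, stringsAsFactors = FALSE))
  })
}

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions (via the generalized
#' distance in [utils::adist()]).
#'
#' @param a,b Strings (vectors recycle elementwise).
#' @return Integer vector of distances.
#' @examples
#' edit_distance("ACGT", "AGT")  # 1
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Collision histogram of non-identical same-hash seed pairs
#'
#' Enumerates all seeds of a sequence, groups them by hash value, and for
#' every *distinct* pair of differing underlying subsequences that share a
#' hash bucket computes the edit distance between their canonical-strand
#' texts. Pairs are deduplicated by text so tandem copy number does not
#' inflate counts quadratically. When more than `max_pairs` distinct
#' non-identical pairs arise, a seeded uniform subsample is tallied and the
#' result is flagged `subsampled`.
#'
#' @param seq One-row data.frame (`name`, `seq`) or a single string.
#' @param params A [seeding_params()]; all three modes are supported so
#'   histograms can be compared across schemes.
#' @param cfg A [simhash_config()]; widths around 16 bits make both chance
#'   and fuzzy collisions observable at the 100 kb scale.
#' @param max_pairs Subsampling threshold.
#' @param rng_seed Seed for the subsample.
#' @return An object of class `collision_histogram`: list with `count`
#'   (named integer vector, edit distance -> pair count), `ratio`
#'   (proportions summing to 1 when any collision exists), `n_pairs`,
#'   `subsampled`.
#' @export
collision_histogram <- function(seq, params, cfg = simhash_config(b = 16L),
                                max_pairs = 200000L, rng_seed = 1L) {
  if (is.data.frame(seq)) seq <- seq$seq[1L]
  seeds <- seed_stream(seq, params, cfg)
  texts <- substring(seq, seeds$start + 1L, seeds$start + seeds$span)
  rev <- seeds$strand == "-"
  texts[rev] <- revcomp_seq(texts[rev])
  pairs_a <- character(0); pairs_b <- character(0)
  by_hash <- split(texts, seeds$hash)
  for (grp in by_hash) {
    utx <- unique(grp)
    if (length(utx) < 2L) next
    cmb <- combn(utx, 2L)
    pairs_a <- c(pairs_a, cmb[1L, ])
    pairs_b <- c(pairs_b, cmb[2L, ])
  }
  n_pairs <- length(pairs_a)
  subsampled <- FALSE
  if (n_pairs > max_pairs) {
    keep <- withr::with_seed(rng_seed, sample.int(n_pairs, max_pairs))
    pairs_a <- pairs_a[keep]; pairs_b <- pairs_b[keep]
    subsampled <- TRUE
  }
  d <- if (length(pairs_a)) edit_distance(pairs_a, pairs_b) else integer(0)
  count <- table(factor(d, levels = sort(unique(d))))
  count <- stats::setNames(as.integer(count), names(count))
  ratio <- if (sum(count) > 0) count / sum(count) else count
  structure(list(count = count, ratio = ratio, n_pairs = n_pairs,
                 subsampled = subsampled, mode = params$mode, n = params$n),
            class = "collision_histogram")
}

#' @export
print.collision_histogram <- function(x, ...) {
  cat(sprintf("collision_histogram: mode %s (n = %d), %d non-identical pair(s)%s\n",
              x$mode, x$n, sum(x$count),
              if (x$subsampled) " [subsampled]" else ""))
  if (length(x$count)) {
    df <- data.frame(edit_distance = names(x$count), count = x$count,
                     ratio = round(x$ratio, 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Same-hash rate of mutated word pairs (fuzzy uplift experiment)
#'
#' Draws `num_pairs` random words of length `L`, mutates each by exactly
#' `d` substitutions at distinct random positions, and hashes both members
#' of every pair under the SimHash scheme (`params_blend`) and under the
#' plain low-collision hash (`params_baseline`). Both members are hashed on
#' their forward orientation as written, so the measured rate reflects the
#' hash schemes rather than canonical-strand flips. Returns the fraction of
#' pairs whose two hash values are equal under each scheme. `d = 0` is
#' allowed for calibration (both rates are then 1).
#'
#' @param num_pairs Number of word pairs.
#' @param L Word length.
#' @param d Number of substitutions per pair (`0 <= d < L`).
#' @param params_blend,params_baseline [seeding_params()] for the two
#'   schemes (only `mode` and `n` are used here).
#' @param cfg A [simhash_config()] shared by both schemes.
#' @param rng_seed Integer seed.
#' @return List with `blend_rate`, `baseline_rate`, `num_pairs`, `L`, `d`,
#'   `b`.
#' @export
uplift_experiment <- function(num_pairs, L, d,
                              params_blend = seeding_params("blend_i", L = L),
                              params_baseline = seeding_params("baseline", L = L),
                              cfg = simhash_config(b = 32L), rng_seed = 1L) {
  stopifnot(num_pairs >= 1, L >= 1)
  if (d >= L) stop("invalid distance: d must be < L")
  if (d < 0) stop("invalid distance: d must be >= 0")
  words <- withr::with_seed(rng_seed, {
    mat <- matrix(sample(BASES, num_pairs * L, replace = TRUE),
                  nrow = num_pairs)
    orig <- apply(mat, 1L, paste, collapse = "")
    mut <- vapply(seq_len(num_pairs), function(i) {
      row <- mat[i, ]
      if (d > 0) {
        pos <- sample.int(L, d)
        for (p in pos) row[p] <- sample(setdiff(BASES, row[p]), 1L)
      }
      paste(row, collapse = "")
    }, character(1))
    list(orig = orig, mut = mut)
  })
  rate <- function(p) {
    h1 <- cpp_hash_words(words$orig, p$mode, p$n, cfg$b, cfg$hash_seed, FALSE)
    h2 <- cpp_hash_words(words$mut, p$mode, p$n, cfg$b, cfg$hash_seed, FALSE)
    mean(h1 == h2)
  }
  list(blend_rate = rate(params_blend),
       baseline_rate = rate(params_baseline),
       num_pairs = num_pairs, L = L, d = d, b = cfg$b)
}

#' Overlap recall and precision against simulated truth
#'
#' A true overlap exists between two reads whose truth intervals on the
#' same genome sequence intersect by at least `min_true_overlap` bases;
#' found pairs are the unordered distinct read pairs reported in the PAF.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param paf PAF data.frame (e.g. from [overlap_sequences()]).
#' @param min_true_overlap Minimum intersection in bases.
#' @return List with `recall`, `precision`, `n_true`, `n_found`,
#'   `no_records` (flag: recall and precision are reported as 0 when the
#'   PAF is empty, with this flag set).
#' @export
overlap_recall <- function(truth, paf, min_true_overlap = 500L) {
  n <- nrow(truth)
  true_pairs <- character(0)
  if (n > 1L) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    i <- idx[, 1L]; j <- idx[, 2L]
    ov <- pmin(truth$end[i], truth$end[j]) - pmax(truth$start[i], truth$start[j])
    keep <- truth$seq_id[i] == truth$seq_id[j] & ov >= min_true_overlap
    i <- i[keep]; j <- j[keep]
    true_pairs <- paste(pmin(truth$name[i], truth$name[j]),
                        pmax(truth$name[i], truth$name[j]))
  }
  found <- unique(paste(pmin(paf$qname, paf$tname),
                        pmax(paf$qname, paf$tname))[paf$qname != paf$tname])
  no_records <- length(found) == 0L
  hit <- intersect(found, true_pairs)
  list(recall = if (length(true_pairs)) length(hit) / length(true_pairs) else 0,
       precision = if (length(found)) length(hit) / length(found) else 0,
       n_true = length(true_pairs), n_found = length(found),
       no_records = no_records)
}
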