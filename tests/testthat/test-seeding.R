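test_that("seeding parameter constraints are enforced", {
  expect_error(seeding_params("blend_i", L = 10, n = 9),
               "neighbor count too large")
  expect_error(seeding_params("blend_s", n = 1), "n >= 2")
  expect_error(seeding_params("baseline", w = 0), "w must be >= 1")
  p <- seeding_params("blend_s")
  expect_equal(p$w, 50L) # HiFi-style default window
  expect_equal(seeding_params("blend_i")$w, 10L)
})

test_that("minimizer selection picks per-window minima, leftmost on ties", {
  # hand-enumerated: AA=0, AT=3, TC=13, CG=6; windows {0,3},{3,13},{13,6}
  m <- minimizers("AATCG", k = 2, w = 2, hasher = function(v, k) v,
                  canonicalize = FALSE)
  expect_equal(m$pos, c(0L, 1L, 3L))
  expect_equal(m$code, c(0, 3, 6))
  # w = 1: every valid k-mer is a minimizer
  m1 <- minimizers("AATCG", k = 2, w = 1, hasher = function(v, k) v,
                   canonicalize = FALSE)
  expect_equal(m1$pos, 0:3)
  # ties go leftmost and repeats are emitted once per selection
  mt <- minimizers("AAAAAA", k = 3, w = 2, hasher = function(v, k) 0,
                   canonicalize = FALSE)
  expect_equal(mt$pos, 0:2) # each of the 3 windows selects its leftmost word
  expect_equal(nrow(minimizers("ACG", k = 5, w = 2)), 0L)
})

test_that("canonical minimizers are strand-symmetric", {
  set.seed(5)
  cfg <- simhash_config(b = 32, hash_seed = 2)
  for (rep in 1:5) {
    s <- rand_seq(300)
    rc <- fuzzyseed:::revcomp_seq(s)
    mf <- minimizers(s, k = 9, w = 4, cfg = cfg)
    mr <- minimizers(rc, k = 9, w = 4, cfg = cfg)
    expect_identical(sort(paste(mf$code, mf$hash)),
                     sort(paste(mr$code, mr$hash)))
  }
})

test_that("windows with ambiguous bases contribute only their valid words", {
  cfg <- simhash_config(b = 16)
  s <- "ACGTTANACGTTA"
  m <- minimizers(s, k = 4, w = 3, cfg = cfg)
  # no selected word may overlap the N
  expect_true(all(m$pos > 6 | m$pos + 4 <= 6))
  expect_equal(nrow(minimizers("NNNNNNNN", k = 4, w = 2, cfg = cfg)), 0L)
})

test_that("R reference minimizers agree with the compiled baseline seeder", {
  set.seed(8)
  cfg <- simhash_config(b = 32, hash_seed = 5)
  s <- rand_seq(2000)
  mm <- minimizers(s, k = 11, w = 8, cfg = cfg)
  ss <- seed_stream(s, seeding_params("baseline", L = 11, w = 8), cfg)
  expect_identical(mm$pos, ss$start)
  expect_identical(mm$hash, ss$hash)
  expect_identical(mm$strand, ss$strand)
})

test_that("blend_i with n = 1 reproduces the baseline minimizer scheme", {
  set.seed(9)
  cfg <- simhash_config(b = 32, hash_seed = 1)
  s <- rand_seq(1500)
  bi <- seed_stream(s, seeding_params("blend_i", L = 13, n = 1, w = 6), cfg)
  bl <- seed_stream(s, seeding_params("baseline", L = 13, w = 6), cfg)
  expect_identical(bi, bl)
})

test_that("blend_i seeds are deterministic with span L and respect bounds", {
  set.seed(10)
  cfg <- simhash_config(b = 64)
  p <- seeding_params("blend_i", L = 15, n = 5, w = 10)
  s <- rand_seq(3000)
  s1 <- seed_stream(s, p, cfg)
  expect_identical(s1, seed_stream(s, p, cfg))
  expect_true(all(s1$span == 15L))
  expect_true(all(s1$start >= 0 & s1$start + s1$span <= nchar(s)))
  expect_true(!is.unsorted(s1$start))
  expect_equal(nrow(seed_stream("", p, cfg)), 0L)
})

test_that("a single substitution changes at most min(k', n) blend_i items", {
  # items are base hashes of overlapping k'-mers; position p of the word is
  # covered by items max(0, p-k'+1) .. min(n-1, p)
  set.seed(12)
  cfg <- simhash_config(b = 32)
  L <- 15L; n <- 5L; kp <- L - n + 1L
  for (rep in 1:20) {
    w1 <- rand_seq(L)
    p <- sample(0:(L - 1), 1)
    chars <- strsplit(w1, "")[[1]]
    chars[p + 1] <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1]), 1)
    w2 <- paste(chars, collapse = "")
    items <- function(w) {
      subs <- substring(w, 1:n, kp:(kp + n - 1))
      base_hash(vapply(subs, function(x) pack_kmer(x)$value, numeric(1)), cfg)
    }
    ndiff <- sum(items(w1) != items(w2))
    expect_lte(ndiff, min(kp, n))
    expect_equal(ndiff, min(n - 1, p) - max(0, p - kp + 1) + 1)
  }
})

test_that("blend_s emits M - n + 1 - broken_runs seeds linking same-strand strobes", {
  set.seed(14)
  cfg <- simhash_config(b = 32, hash_seed = 3)
  k <- 7L; w <- 3L; n <- 3L
  for (rep in 1:10) {
    s <- rand_seq(400)
    mm <- minimizers(s, k = k, w = w, cfg = cfg)
    M <- nrow(mm)
    broken <- 0L
    if (M >= n) {
      for (i in seq_len(M - n + 1L)) {
        same <- sum(mm$strand[i:M] == mm$strand[i])
        if (same < n) broken <- broken + 1L
      }
    }
    seeds <- seed_stream(s, seeding_params("blend_s", k = k, w = w, n = n), cfg)
    expect_equal(nrow(seeds), max(0L, M - n + 1L - broken))
    expect_true(all(seeds$span >= k))
  }
})

test_that("blend_s links exactly n strobes and mutating one changes one item", {
  cfg <- simhash_config(b = 32, hash_seed = 3)
  set.seed(15)
  # a sequence with exactly 3 same-strand minimizers and n = 2 gives 2 seeds
  found <- FALSE
  for (rep in 1:500) {
    s <- rand_seq(sample(16:26, 1))
    mm <- minimizers(s, k = 7, w = 6, cfg = cfg)
    if (nrow(mm) == 3 && length(unique(mm$strand)) == 1) {
      seeds <- seed_stream(s, seeding_params("blend_s", k = 7, w = 6, n = 2), cfg)
      expect_equal(nrow(seeds), 2L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # a substitution inside one linked k-mer that leaves the minimizer
  # selection unchanged alters exactly one of the n item hashes, and only
  # the seeds linking the mutated strobe change their SimHash value
  checked <- FALSE
  for (rep in 1:5000) {
    s <- rand_seq(120)
    mm <- minimizers(s, k = 7, w = 3, cfg = cfg)
    p <- sample(nchar(s), 1) - 1L
    chars <- strsplit(s, "")[[1]]
    chars[p + 1] <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1]), 1)
    s2 <- paste(chars, collapse = "")
    mm2 <- minimizers(s2, k = 7, w = 3, cfg = cfg)
    if (!identical(mm$pos, mm2$pos) || !identical(mm$strand, mm2$strand))
      next
    if (sum(mm$code != mm2$code) != 1) next
    expect_equal(sum(mm$hash != mm2$hash), 1) # one linked item hash changes
    pm <- seeding_params("blend_s", k = 7, w = 3, n = 3)
    s1_seeds <- seed_stream(s, pm, cfg)
    s2_seeds <- seed_stream(s2, pm, cfg)
    expect_equal(nrow(s1_seeds), nrow(s2_seeds))
    # seeds not linking the changed strobe keep their hash
    changed_pos <- mm$pos[mm$code != mm2$code]
    untouched <- s1_seeds$start + s1_seeds$span <= changed_pos |
      s1_seeds$start > changed_pos
    expect_identical(s1_seeds$hash[untouched], s2_seeds$hash[untouched])
    checked <- TRUE
    break
  }
  expect_true(checked)
})

test_that("identical substrings longer than L + w - 1 share a seed hash", {
  set.seed(16)
  cfg <- simhash_config(b = 64)
  p <- seeding_params("blend_i", L = 15, n = 5, w = 10)
  for (rep in 1:5) {
    core <- rand_seq(15 + 10 - 1) # L + w - 1: guarantees one shared window
    a <- paste0(rand_seq(50), core, rand_seq(50))
    b <- paste0(rand_seq(80), core, rand_seq(20))
    ha <- seed_stream(a, p, cfg)$hash
    hb <- seed_stream(b, p, cfg)$hash
    expect_gt(length(intersect(ha, hb)), 0)
  }
})

test_that("every window of valid words contributes a seed (window guarantee)", {
  set.seed(17)
  cfg <- simhash_config(b = 64)
  L <- 15L; w <- 10L
  s <- rand_seq(2000)
  seeds <- seed_stream(s, seeding_params("blend_i", L = L, w = w, n = 5), cfg)
  # consecutive selected positions can be at most w apart
  expect_true(all(diff(seeds$start) <= w))
  expect_lt(seeds$start[1], w)
})

test_that("fuzzy blend_i hashing matches mutated words more often than baseline", {
  res <- uplift_experiment(2000, 15, 1, cfg = simhash_config(b = 16),
                           rng_seed = 7)
  expect_gt(res$blend_rate, res$baseline_rate)
})

test_that("seed_stream dispatches modes and rejects unknown ones", {
  cfg <- simhash_config(b = 32)
  s <- paste(rep("ACGGTCTAAT", 30), collapse = "")
  base <- seed_stream(s, seeding_params("baseline", L = 11, w = 4), cfg)
  # baseline hashes are the base hashes of the selected canonical words
  texts <- substring(s, base$start + 1, base$start + base$span)
  texts[base$strand == "-"] <- fuzzyseed:::revcomp_seq(texts[base$strand == "-"])
  vals <- vapply(texts, function(t) pack_kmer(t)$value, numeric(1))
  expect_identical(base$hash, unname(base_hash(vals, cfg)))
  expect_error(seeding_params("nonsense"), "arg")
  # blend_i and baseline can select different minimizer positions
  set.seed(18)
  different <- FALSE
  for (rep in 1:20) {
    r <- rand_seq(400)
    a <- seed_stream(r, seeding_params("blend_i", L = 11, n = 5, w = 6), cfg)
    b <- seed_stream(r, seeding_params("baseline", L = 11, w = 6), cfg)
    if (!identical(a$start, b$start)) { different <- TRUE; break }
  }
  expect_true(different)
})
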