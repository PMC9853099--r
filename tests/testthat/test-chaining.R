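cfgc <- simhash_config(b = 64, hash_seed = 4)
pc <- seeding_params("baseline", L = 13, w = 4)

test_that("self-query yields a pure diagonal of anchors, counted by lookup", {
  set.seed(31)
  s <- rand_seq(1200)
  idx <- suppressMessages(build_index(c(t = s), pc, cfgc, max_occ = Inf))
  anc <- collect_anchors(idx, s, "q")
  expect_true(all(anc$q_start == anc$t_start))
  expect_true(all(anc$strand_pair == "same"))
  # recount oracle: anchors = sum of per-seed lookup list lengths
  seeds <- seed_stream(s, pc, cfgc)
  expect_equal(nrow(anc),
               sum(vapply(seeds$hash, function(h)
                 nrow(query_index(idx, h)), integer(1))))
  # sorted as promised
  expect_false(is.unsorted(order(anc$target_id, anc$strand_pair,
                                 anc$t_start, anc$q_start)))
  # disjoint query shares nothing
  anc0 <- collect_anchors(idx, strrep("A", 200), "q")
  expect_equal(nrow(anc0), 0L)
})

test_that("self-matches are excluded in all-vs-all mode", {
  set.seed(32)
  s <- rand_seq(800)
  idx <- suppressMessages(build_index(c(r1 = s), pc, cfgc))
  anc <- collect_anchors(idx, s, "r1", exclude_self = TRUE)
  expect_false(any(anc$target_id == "r1" & anc$q_start == anc$t_start &
                     anc$strand_pair == "same"))
})

test_that("anchor collection rejects a mismatched index", {
  idx <- suppressMessages(build_index(c(t = rand_seq(200)), pc, cfgc))
  expect_error(collect_anchors(idx, "ACGT", params = seeding_params("blend_i")),
               "incompatible index")
  expect_error(collect_anchors(idx, "ACGT", cfg = simhash_config(b = 32)),
               "incompatible index")
})

test_that("perfect diagonals chain into a single full-length chain", {
  anc <- data.frame(target_id = "t",
                    q_start = seq(0L, 900L, by = 100L),
                    t_start = seq(50L, 950L, by = 100L),
                    span = 13L, q_strand = "+", strand_pair = "same",
                    stringsAsFactors = FALSE)
  ch <- chain_anchors(anc, max_gap = 5000, min_chain_score = 40,
                      min_anchors = 3)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$anchors), 10)
  expect_equal(ch[[1]]$score, 130) # zero drift: sum of spans
  expect_length(chain_anchors(anc[0, ]), 0)
})

test_that("chains never violate monotone coordinates and score bounds", {
  set.seed(33)
  for (rep in 1:30) {
    m <- sample(2:30, 1)
    anc <- data.frame(target_id = "t",
                      q_start = sample(0:400, m),
                      t_start = sample(0:400, m),
                      span = sample(5:20, m, replace = TRUE),
                      q_strand = "+",
                      strand_pair = sample(c("same", "opposite"), m,
                                           replace = TRUE),
                      stringsAsFactors = FALSE)
    anc <- anc[order(anc$target_id, anc$strand_pair, anc$t_start,
                     anc$q_start), ]
    for (ch in chain_anchors(anc, max_gap = 100, min_chain_score = 1,
                             min_anchors = 1)) {
      a <- ch$anchors
      expect_true(all(diff(a$q_start) > 0))
      if (ch$strand_pair == "same") expect_true(all(diff(a$t_start) > 0))
      else expect_true(all(diff(a$t_start) < 0))
      expect_lte(ch$score, sum(a$span))
    }
  }
})

test_that("the chaining DP matches exhaustive search on small instances", {
  set.seed(34)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    mg <- sample(c(20L, 50L, 200L), 1)
    anc <- data.frame(target_id = "t",
                      q_start = sample(0:80, m),
                      t_start = sample(0:80, m),
                      span = sample(3:15, m, replace = TRUE),
                      q_strand = "+", strand_pair = "same",
                      stringsAsFactors = FALSE)
    anc <- anc[order(anc$t_start, anc$q_start), ]
    ch <- chain_anchors(anc, max_gap = mg, min_chain_score = 1,
                        min_anchors = 1)
    best_dp <- max(vapply(ch, `[[`, numeric(1), "score"))
    best_oracle <- oracle_chain_best(anc$q_start, anc$t_start, anc$span, mg)
    expect_equal(best_dp, best_oracle)
  }
})

test_that("a full-length self chain emits the identity PAF record", {
  set.seed(35)
  s <- rand_seq(1000)
  idx <- suppressMessages(build_index(c(g = s), pc, cfgc))
  paf <- map_sequences(idx, c(q = s))
  expect_equal(nrow(paf), 1)
  expect_equal(paf$qstart, 0L)
  expect_equal(paf$qend, 1000L)
  expect_equal(paf$tstart, 0L)
  expect_equal(paf$tend, 1000L)
  expect_equal(paf$strand, "+")
  expect_equal(paf$alen, 1000L)
  # zero chains produce zero records
  expect_equal(nrow(chains_to_records(list(), "q", 10, c(t = 10))), 0L)
})

test_that("reverse-complement queries map on the minus strand with forward target coords", {
  set.seed(36)
  s <- rand_seq(2000)
  frag <- substring(s, 501, 1500)
  paf <- map_sequences(suppressMessages(build_index(c(g = s), pc, cfgc)),
                       c(q = fuzzyseed:::revcomp_seq(frag)))
  expect_equal(nrow(paf), 1)
  expect_equal(paf$strand, "-")
  expect_equal(paf$tstart, 500L)
  expect_equal(paf$tend, 1500L)
  expect_equal(paf$qstart, 0L)
  expect_equal(paf$qend, 1000L)
  expect_lt(paf$tstart, paf$tend)
})

test_that("mapping quality separates unique from ambiguous placements", {
  set.seed(37)
  core <- rand_seq(600)
  genome <- paste0(rand_seq(200), core, rand_seq(300), core, rand_seq(200))
  idx <- suppressMessages(build_index(c(g = genome), pc, cfgc, max_occ = Inf))
  amb <- map_sequences(idx, c(q = core))
  expect_gte(nrow(amb), 2)
  expect_equal(max(amb$mapq), 0) # two equal-score placements: no confidence
  uniq <- map_sequences(idx, c(u = rand_seq(600)))
  expect_equal(nrow(uniq), 0)
  s2 <- substring(genome, 1, 400) # unique flank
  one <- map_sequences(idx, c(v = s2))
  expect_gte(max(one$mapq), 40 - 40 * max(0, nrow(one) - 1))
})

test_that("all-vs-all overlap reports are coordinate-mirrored", {
  set.seed(38)
  g <- rand_seq(3000)
  reads <- c(a = substring(g, 1, 1800), b = substring(g, 1001, 2800))
  paf <- overlap_sequences(reads, pc, cfgc)
  ab <- paf[paf$qname == "a" & paf$tname == "b", ]
  ba <- paf[paf$qname == "b" & paf$tname == "a", ]
  expect_equal(nrow(ab), 1)
  expect_equal(nrow(ba), 1)
  expect_equal(ab$nmatch, ba$nmatch) # same anchor set, mirrored
  expect_equal(ab$qstart, ba$tstart)
  expect_equal(ab$qend, ba$tend)
})
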