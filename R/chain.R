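#' Collect anchors for a query sequence
#'
#' Extracts the query's seeds and, for each one, turns every index record
#' under its hash value into one anchor `(target_id, q_start, t_start, span,
#' strand_pair)`. `strand_pair` is `"same"` when the query seed and target
#' record lie on the same strand. In all-vs-all mode (`exclude_self = TRUE`,
#' query present among the targets) the trivial self-matches -- same
#' sequence name, same coordinate, same strand -- are removed.
#'
#' @param index A [build_index()] result.
#' @param query A single nucleotide string.
#' @param query_name Name of the query sequence (used for self-exclusion).
#' @param params,cfg Must be identical to the parameters the index was built
#'   with; a mismatch signals an incompatible index. Default: taken from the
#'   index.
#' @param exclude_self Drop self-matches (all-vs-all mode).
#' @return A data.frame of anchors sorted by `(target_id, strand_pair,
#'   t_start, q_start)`. The anchor `span` is the smaller of the two seed
#'   spans (they can differ between fuzzy-matching `blend_s` seeds).
#' @export
collect_anchors <- function(index, query, query_name = "query",
                            params = index$params, cfg = index$cfg,
                            exclude_self = FALSE) {
  stopifnot(inherits(index, "seed_index"))
  if (!identical(params, index$params) || !identical(cfg, index$cfg))
    stop("incompatible index: seeding parameters or hash configuration differ")
  qseeds <- seed_stream(query, params, cfg)
  empty <- data.frame(target_id = character(0), q_start = integer(0),
                      t_start = integer(0), span = integer(0),
                      q_strand = character(0),
                      strand_pair = character(0), stringsAsFactors = FALSE)
  if (nrow(qseeds) == 0L) return(empty)
  hits <- mget(qseeds$hash, envir = index$table,
               ifnotfound = list(integer(0)))
  nh <- lengths(hits)
  if (sum(nh) == 0L) return(empty)
  qi <- rep.int(seq_len(nrow(qseeds)), nh)
  ri <- unlist(hits, use.names = FALSE)
  rec <- index$records
  anchors <- data.frame(
    target_id = rec$seq_id[ri],
    q_start = qseeds$start[qi],
    t_start = rec$start[ri],
    span = pmin(qseeds$span[qi], rec$span[ri]),
    q_strand = qseeds$strand[qi],
    strand_pair = ifelse(qseeds$strand[qi] == rec$strand[ri], "same", "opposite"),
    stringsAsFactors = FALSE)
  if (exclude_self) {
    self <- anchors$target_id == query_name &
      anchors$t_start == anchors$q_start & anchors$strand_pair == "same"
    anchors <- anchors[!self, , drop = FALSE]
  }
  anchors <- anchors[order(anchors$target_id, anchors$strand_pair,
                           anchors$t_start, anchors$q_start), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

#' Chain anchors into co-linear groups
#'
#' Per `(target_id, strand_pair)` group, a dynamic program maximizes
#' `sum(anchor spans) - sum(gap costs)` over co-linear anchor subsets, where
#' the gap cost between consecutive anchors is `|dq - dt|` (diagonal drift)
#' and transitions with `dq` or `dt` exceeding `max_gap`, or non-monotone
#' in either coordinate, are forbidden. Same-strand chains are strictly
#' increasing in both `q_start` and `t_start`; opposite-strand chains
#' increase in `q` and decrease in `t`. Chains are extracted best-score
#' first with anchor consumption; chains below `min_chain_score` or with
#' fewer than `min_anchors` anchors are discarded.
#'
#' @param anchors Anchor data.frame from [collect_anchors()].
#' @param max_gap Maximum per-coordinate gap between consecutive anchors.
#' @param min_chain_score Minimum reported chain score.
#' @param min_anchors Minimum anchors per reported chain.
#' @return A list of chains, each a list with `target_id`, `strand_pair`,
#'   `anchors` (data.frame, chain order), `score`, `q_span`, `t_span`
#'   (half-open `[lo, hi)` on forward coordinates). Sorted by decreasing
#'   score.
#' @export
chain_anchors <- function(anchors, max_gap = 5000L, min_chain_score = 40L,
                          min_anchors = 3L) {
  if (nrow(anchors) == 0L) return(list())
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$target_id, anchors$strand_pair, sep = "\r"))
  chains <- list()
  for (g in groups) {
    a <- anchors[g, , drop = FALSE]
    opposite <- a$strand_pair[1L] == "opposite"
    # flip target coordinates of opposite-strand groups so chains are
    # strictly increasing in both coordinates for the DP
    tt <- if (opposite) -(a$t_start + a$span) else a$t_start
    ord <- order(tt, a$q_start)
    a <- a[ord, , drop = FALSE]
    tt <- tt[ord]
    res <- cpp_chain(a$q_start, tt, a$span,
                     as.integer(max_gap), as.integer(min_chain_score),
                     as.integer(min_anchors))
    ids <- res$chain
    for (ci in seq_along(res$score)) {
      rows <- which(ids == ci)
      ca <- a[rows, , drop = FALSE]
      chains[[length(chains) + 1L]] <- list(
        target_id = ca$target_id[1L],
        strand_pair = ca$strand_pair[1L],
        anchors = ca,
        score = res$score[ci],
        q_span = c(min(ca$q_start), max(ca$q_start + ca$span)),
        t_span = c(min(ca$t_start), max(ca$t_start + ca$span)))
    }
  }
  if (length(chains) > 1L)
    chains <- chains[order(vapply(chains, `[[`, numeric(1), "score"),
                           decreasing = TRUE)]
  chains
}

#' Convert chains to PAF records
#'
#' One 12-column PAF row per chain. The residue-matches column is the sum of
#' anchor spans, the block length is the longer of the two spanned
#' intervals, and mapping quality is `floor(40 * (1 - s2 / s1))` clamped to
#' `[0, 60]`, with `s2` the best score among the query's *other* chains (0
#' when there is none). By default the reported interval is extended from
#' the chained anchors along the chain diagonal to the sequence ends
#' (`min(head room on query, head room on target)` at each side), the usual
#' overlap-extension convention; set `extend = FALSE` for bare anchor
#' bounds. Reverse-strand records report target coordinates on the forward
#' strand.
#'
#' @param chains List from [chain_anchors()] (one query).
#' @param query_name,query_len Query identity.
#' @param target_lengths Named vector of target lengths (e.g.
#'   `index$target_lengths`).
#' @param extend Extend intervals along the diagonal to the sequence ends.
#' @return A PAF data.frame (see [write_paf()] for columns); zero rows when
#'   `chains` is empty.
#' @export
chains_to_records <- function(chains, query_name, query_len, target_lengths,
                              extend = TRUE) {
  if (length(chains) == 0L) return(empty_paf())
  scores <- vapply(chains, `[[`, numeric(1), "score")
  recs <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    tlen <- unname(target_lengths[[ch$target_id]])
    qs <- ch$q_span[1L]; qe <- ch$q_span[2L]
    ts <- ch$t_span[1L]; te <- ch$t_span[2L]
    if (extend) {
      if (ch$strand_pair == "same") {
        d <- min(qs, ts); qs <- qs - d; ts <- ts - d
        d <- min(query_len - qe, tlen - te); qe <- qe + d; te <- te + d
      } else {
        d <- min(qs, tlen - te); qs <- qs - d; te <- te + d
        d <- min(query_len - qe, ts); qe <- qe + d; ts <- ts - d
      }
    }
    s2 <- if (length(scores) > 1L) max(scores[-i]) else 0
    mapq <- max(0L, min(60L, as.integer(floor(40 * (1 - s2 / scores[i])))))
    data.frame(qname = query_name, qlen = query_len, qstart = qs, qend = qe,
               strand = if (ch$strand_pair == "same") "+" else "-",
               tname = ch$target_id, tlen = tlen, tstart = ts, tend = te,
               nmatch = sum(ch$anchors$span),
               alen = max(qe - qs, te - ts),
               mapq = mapq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Map query sequences against a seed index
#'
#' Runs anchor collection, chaining and PAF conversion for each query.
#'
#' @param index A [build_index()] result.
#' @param queries Data.frame with `name` and `seq` columns (e.g. from
#'   [read_sequences()]), or a named character vector.
#' @param max_gap,min_chain_score,min_anchors See [chain_anchors()].
#' @param exclude_self Drop self-matches and same-name records (all-vs-all).
#' @param extend See [chains_to_records()].
#' @return A PAF data.frame over all queries.
#' @examples
#' idx <- build_index(c(g = paste(rep("ACGGTCTA", 40), collapse = "")),
#'                    seeding_params("baseline", L = 7, w = 3),
#'                    simhash_config(b = 32))
#' map_sequences(idx, c(r1 = paste(rep("ACGGTCTA", 10), collapse = "")),
#'               min_chain_score = 10)
#' @export
map_sequences <- function(index, queries, max_gap = 5000L,
                          min_chain_score = 40L, min_anchors = 3L,
                          exclude_self = FALSE, extend = TRUE) {
  if (is.character(queries))
    queries <- data.frame(name = names(queries), seq = unname(queries),
                          stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(queries)), function(i) {
    anc <- collect_anchors(index, queries$seq[i], queries$name[i],
                           exclude_self = exclude_self)
    ch <- chain_anchors(anc, max_gap, min_chain_score, min_anchors)
    chains_to_records(ch, queries$name[i], nchar(queries$seq[i]),
                      index$target_lengths, extend = extend)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_paf())
  rownames(res) <- NULL
  res
}

#' All-vs-all read overlapping
#'
#' Indexes the read set and maps every read against it with self-matches
#' suppressed; mirrored records (A over B and B over A) are both reported,
#' as consumers of all-vs-all PAF expect.
#'
#' @param reads Data.frame with `name`/`seq`, or named character vector.
#' @param params,cfg Seeding parameters and hash configuration.
#' @param max_occ Frequency filter for the internal index.
#' @inheritParams map_sequences
#' @return A PAF data.frame.
#' @export
overlap_sequences <- function(reads, params, cfg = simhash_config(),
                              max_occ = 1000L, max_gap = 5000L,
                              min_chain_score = 40L, min_anchors = 3L,
                              extend = TRUE) {
  if (is.character(reads))
    reads <- data.frame(name = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  idx <- suppressMessages(build_index(reads, params, cfg, max_occ = max_occ))
  map_sequences(idx, reads, max_gap, min_chain_score, min_anchors,
                exclude_self = TRUE, extend = extend)
}
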