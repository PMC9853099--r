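#' Build a seed index over target sequences
#'
#' Extracts seeds from every target with [seed_stream()] and stores their
#' coordinate records in a hash table keyed by seed hash value, so that a
#' query seed finds every exact *and* fuzzy match (same hash value) with a
#' single lookup. The index stores no sequence text, only `(seq_id, start,
#' span, strand)` records, sorted by `(seq_id, start)` under each key.
#'
#' @param targets Targets as a data.frame with columns `name` and `seq`
#'   (e.g. from [read_sequences()]), or a named character vector of
#'   sequences.
#' @param params A [seeding_params()].
#' @param cfg A [simhash_config()].
#' @param max_occ Drop keys whose record list exceeds this length (repeat
#'   masking); `Inf` disables. Applied after full insertion.
#' @return An object of class `seed_index`: list with `table` (environment
#'   mapping hash to integer record rows), `records` (data.frame),
#'   `params`, `cfg`, `target_lengths`, `n_seeds`, `n_dropped_keys`.
#' @examples
#' idx <- build_index(c(t1 = "ACGTACGTTAGGACCA"),
#'                    seeding_params("baseline", L = 5, w = 2),
#'                    simhash_config(b = 16))
#' idx
#' @export
build_index <- function(targets, params, cfg = simhash_config(), max_occ = 1000L) {
  stopifnot(inherits(params, "seeding_params"), inherits(cfg, "simhash_config"))
  if (is.character(targets)) {
    if (is.null(names(targets)) || any(!nzchar(names(targets))))
      stop("targets given as a character vector must be named")
    targets <- data.frame(name = names(targets), seq = unname(targets),
                          stringsAsFactors = FALSE)
  }
  if (nrow(targets) == 0L) stop("no targets")
  if (anyDuplicated(targets$name)) stop("duplicate target names")
  per_target <- lapply(seq_len(nrow(targets)), function(i) {
    s <- seed_stream(targets$seq[i], params, cfg)
    if (nrow(s)) cbind(seq_id = targets$name[i], s, stringsAsFactors = FALSE)
    else NULL
  })
  per_target <- per_target[!vapply(per_target, is.null, logical(1))]
  records <- if (length(per_target)) do.call(rbind, per_target)
    else data.frame(seq_id = character(0), start = integer(0), span = integer(0),
                    strand = character(0), hash = character(0),
                    stringsAsFactors = FALSE)
  ord <- order(records$seq_id, records$start)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  tab <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(records)) list2env(split(seq_len(nrow(records)), records$hash), tab)
  idx <- structure(list(table = tab, records = records, params = params,
                        cfg = cfg,
                        target_lengths = stats::setNames(nchar(targets$seq),
                                                         targets$name),
                        n_seeds = nrow(records), n_dropped_keys = 0L),
                   class = "seed_index")
  if (is.finite(max_occ)) idx <- filter_frequent(idx, max_occ) else idx
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf(paste0("seed_index: %d target(s), %d seed record(s), %d key(s)",
                     " (%d dropped by frequency filter)\n"),
              length(x$target_lengths), nrow(x$records),
              length(ls(x$table)), x$n_dropped_keys))
  print(x$params)
  print(x$cfg)
  invisible(x)
}

#' Drop over-frequent seed hash keys
#'
#' Removes keys whose record list is longer than `max_occ` -- the standard
#' repeat-masking step that keeps anchor collection near-linear on
#' repetitive targets. Never lengthens a list or adds a key.
#'
#' @param index A [build_index()] result.
#' @param max_occ Maximum allowed records per key (>= 1).
#' @return The filtered `seed_index`; the count of dropped keys is added to
#'   `n_dropped_keys` and reported via `message()`.
#' @export
filter_frequent <- function(index, max_occ) {
  stopifnot(inherits(index, "seed_index"))
  if (!is.finite(max_occ)) return(index)
  if (max_occ < 1L) stop("max_occ must be >= 1")
  entries <- as.list(index$table)
  lens <- lengths(entries)
  drop <- sum(lens > max_occ)
  # rebuild rather than mutate: the table environment may be shared with
  # the unfiltered index object
  tab <- new.env(hash = TRUE, parent = emptyenv())
  list2env(entries[lens <= max_occ], tab)
  index$table <- tab
  index$n_dropped_keys <- index$n_dropped_keys + drop
  message(sprintf("filter_frequent: dropped %d key(s) with more than %s records",
                  drop, format(max_occ)))
  index
}

#' Query the seed index with one hash value
#'
#' One hash-table lookup, no scanning of other keys: fuzzy matching lives
#' entirely in the hashing scheme, which gives similar seeds the same key.
#'
#' @param index A `seed_index`.
#' @param hash A single hex hash string.
#' @return A data.frame of index records (`seq_id`, `start`, `span`,
#'   `strand`), empty when the key is absent.
#' @export
query_index <- function(index, hash) {
  stopifnot(inherits(index, "seed_index"), is.character(hash), length(hash) == 1L)
  rows <- index$table[[hash]]
  if (is.null(rows))
    return(index$records[0L, c("seq_id", "start", "span", "strand"), drop = FALSE])
  index$records[rows, c("seq_id", "start", "span", "strand"), drop = FALSE]
}
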