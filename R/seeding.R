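#' Seeding parameters
#'
#' Bundles the knobs of the three seeding modes.
#'
#' * `blend_i` -- minimizer selection over words of length `L` with window
#'   `w`, where each word's selection value (and final seed hash) is the
#'   SimHash of the base hashes of its `n` overlapping sub-k-mers of length
#'   `L - n + 1`, read on the canonical orientation of the word.
#'   Substitution-sensitive: one changed base perturbs at most
#'   `min(L - n + 1, n)` of the `n` items.
#' * `blend_s` -- minimizers of length `k` (window `w`) are linked
#'   strobemer-style: each minimizer starts a seed joining the next `n - 1`
#'   minimizers that share its orientation (opposite-strand minimizers are
#'   passed over, keeping the seed strand well defined; a start with too few
#'   same-strand successors is a broken run and emits nothing). The seed's
#'   items are the `n` linked k-mer hashes and its hash their SimHash.
#'   Tolerates indels between strobes and whole mismatching strobes.
#' * `baseline` -- plain minimizers of length `L`, hashed with the
#'   low-collision base hash; only exact-matching seeds collide.
#'
#' Defaults follow the two regimes the schemes are intended for: `blend_i`
#' with `L = 15, n = 5, w = 10` (erroneous long reads), `blend_s` with
#' `k = 19, n = 5, w = 50` (accurate HiFi-style reads, where wider sampling
#' windows are affordable).
#'
#' @param mode One of `"blend_i"`, `"blend_s"`, `"baseline"`.
#' @param L Seed (word) length in bases for `blend_i`/`baseline`, at most 31.
#' @param k Length of each selected/linked k-mer for `blend_s`, at most 31.
#' @param w Minimizer window: number of consecutive words per window.
#' @param n Number of set items per seed: overlapping sub-k-mers (`blend_i`,
#'   requires `L - n + 1 >= 4`) or linked k-mers (`blend_s`, requires
#'   `n >= 2`).
#' @return An object of class `seeding_params`.
#' @examples
#' seeding_params("blend_i")
#' seeding_params("blend_s", k = 19, n = 5, w = 50)
#' @export
seeding_params <- function(mode = c("blend_i", "blend_s", "baseline"),
                           L = 15L, k = 19L, w = NULL, n = 5L) {
  mode <- match.arg(mode)
  L <- as.integer(L); k <- as.integer(k); n <- as.integer(n)
  if (is.null(w)) w <- if (mode == "blend_s") 50L else 10L
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1")
  if (L < 1L || L > 31L || k < 1L || k > 31L) stop("L and k must be in 1..31")
  if (mode == "blend_i") {
    if (n < 1L) stop("n must be >= 1")
    if (L - n + 1L < 4L) stop("neighbor count too large for seed length")
  }
  if (mode == "blend_s" && n < 2L) stop("blend_s requires n >= 2 linked k-mers")
  structure(list(mode = mode, L = L, k = k, w = w, n = n),
            class = "seeding_params")
}

#' @export
print.seeding_params <- function(x, ...) {
  word <- if (x$mode == "blend_s") sprintf("k = %d", x$k) else sprintf("L = %d", x$L)
  cat(sprintf("seeding_params: mode %s, %s, w = %d, n = %d\n", x$mode, word, x$w, x$n))
  invisible(x)
}

#' Minimizer selection (reference implementation)
#'
#' Selects, for every window of `w` consecutive k-mers, the k-mer with the
#' minimum hash value; consecutive windows sharing the same minimum emit it
#' once, and ties within a window go to the leftmost occurrence. Windows
#' containing unpackable (ambiguous-base) or palindromic words contribute
#' only their valid k-mers; windows with no valid k-mer emit nothing. When
#' fewer than `w` k-mer positions exist, the available positions form a
#' single window.
#'
#' This pure-R version accepts an arbitrary `hasher` and exists as the
#' flexible reference for the compiled production path in [seed_stream()].
#'
#' @param seq A nucleotide string.
#' @param k Word length (at most 26 here, so packed values stay exact).
#' @param w Window length in words.
#' @param hasher `function(value, k)` mapping a packed k-mer value to a
#'   comparable hash (numeric or fixed-width character). Default: the base
#'   hash under `cfg`.
#' @param cfg A [simhash_config()] used by the default hasher.
#' @param canonicalize If `TRUE` (default) hash canonical codes and skip
#'   palindromes; if `FALSE`, hash forward-strand codes as written
#'   (useful for worked examples).
#' @return A data.frame with columns `pos` (0-based), `code`, `strand`,
#'   `hash`, sorted by position. Empty when `seq` is shorter than `k`.
#' @examples
#' minimizers("AATCG", k = 2, w = 2, hasher = function(v, k) v,
#'            canonicalize = FALSE)
#' @export
minimizers <- function(seq, k, w, hasher = NULL, cfg = simhash_config(),
                       canonicalize = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(k); w <- as.integer(w)
  if (k < 1L || k > 26L) stop("k must be in 1..26")
  if (w < 1L) stop("w must be >= 1")
  if (is.null(hasher)) hasher <- function(value, k) base_hash(value, cfg)
  m <- nchar(seq)
  empty <- data.frame(pos = integer(0), code = numeric(0),
                      strand = character(0), hash = character(0),
                      stringsAsFactors = FALSE)
  if (m < k) return(empty)
  P <- m - k + 1L
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T")) - 1L
  pow <- 4^(rev(seq_len(k)) - 1)
  val <- rep(NA_real_, P)
  strand <- rep(NA_character_, P)
  for (p in seq_len(P)) {
    cc <- codes[p:(p + k - 1L)]
    if (anyNA(cc)) next
    fwd <- sum(cc * pow)
    if (!canonicalize) {
      val[p] <- fwd
      strand[p] <- "+"
      next
    }
    rc <- sum(rev(3 - cc) * pow)
    if (fwd < rc) { val[p] <- fwd; strand[p] <- "+" }
    else if (rc < fwd) { val[p] <- rc; strand[p] <- "-" }
    # palindromic words stay NA (skipped)
  }
  valid <- which(!is.na(val))
  if (length(valid) == 0L) return(empty)
  hv <- hasher(val[valid], k)
  # keep the hasher's own type: numeric and fixed-width character both order
  # correctly, but numeric must not be compared as text
  hashes <- rep(if (is.numeric(hv)) NA_real_ else NA_character_, P)
  hashes[valid] <- hv
  nwin <- if (P >= w) P - w + 1L else 1L
  wsz <- min(w, P)
  sel <- integer(0)
  last <- -1L
  for (p0 in seq_len(nwin)) {
    idx <- p0:(p0 + wsz - 1L)
    idx <- idx[!is.na(hashes[idx])]
    if (length(idx) == 0L) next
    best <- idx[which(hashes[idx] == min(hashes[idx]))[1L]]
    if (best != last) { sel <- c(sel, best); last <- best }
  }
  data.frame(pos = sel - 1L, code = val[sel], strand = strand[sel],
             hash = hashes[sel], stringsAsFactors = FALSE)
}

#' Extract seeds from a sequence
#'
#' Dispatches on `params$mode` to minimizer (`baseline`), SimHash-over-
#' sub-k-mers (`blend_i`) or linked-minimizer (`blend_s`) seeding; see
#' [seeding_params()] for the schemes. Output rows are sorted by start.
#'
#' @param seq A nucleotide string.
#' @param params A [seeding_params()].
#' @param cfg A [simhash_config()].
#' @return A data.frame with columns `start` (0-based), `span` (bases),
#'   `strand` (`"+"`/`"-"`), `hash` (hex). `blend_i`/`baseline` seeds have
#'   `span = L`; `blend_s` seeds cover first-strobe start to last-strobe end.
#' @examples
#' seed_stream(paste(rep("ACGGT", 20), collapse = ""),
#'             seeding_params("blend_i", L = 8, n = 3, w = 4),
#'             simhash_config(b = 16))
#' @export
seed_stream <- function(seq, params, cfg = simhash_config()) {
  stopifnot(inherits(params, "seeding_params"), inherits(cfg, "simhash_config"))
  stopifnot(is.character(seq), length(seq) == 1L)
  word_len <- if (params$mode == "blend_s") params$k else params$L
  n_items <- if (params$mode == "baseline") 1L else params$n
  cpp_seed_stream(seq, params$mode, word_len, params$w, n_items,
                  cfg$b, cfg$hash_seed)
}

#' @rdname seed_stream
#' @export
blend_i_seeds <- function(seq, params, cfg = simhash_config()) {
  if (params$mode != "blend_i") stop("params$mode must be 'blend_i'")
  seed_stream(seq, params, cfg)
}

#' @rdname seed_stream
#' @export
blend_s_seeds <- function(seq, params, cfg = simhash_config()) {
  if (params$mode != "blend_s") stop("params$mode must be 'blend_s'")
  seed_stream(seq, params, cfg)
}

# reverse complement of a plain nucleotide string (case preserved per base)
revcomp_seq <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
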